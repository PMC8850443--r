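#' Canonical simulation-record schema
#'
#' Returns the canonical column set of a harmonized yield-projection corpus
#' together with the storage type of each column. Yields are t/ha,
#' temperatures degrees C, precipitation mm, impacts percent; one unit system
#' per corpus, normalized at read time.
#'
#' @return Named character vector mapping column name to type
#'   (`"character"`, `"integer"`, `"numeric"`, `"logical"`).
#' @export
corpus_schema <- function() {
  c(study_id = "character", ref_label = "character", pub_year = "integer",
    crop = "character", country = "character", site_label = "character",
    lat = "numeric", lon = "numeric", scale = "character",
    region_group = "character", climate_family = "character",
    scenario = "character", esm = "character",
    future_start = "integer", future_end = "integer", future_mid = "integer",
    base_start = "integer", base_end = "integer", base_mid = "integer",
    Yb = "numeric", Yf = "numeric", YI_raw = "numeric", YI_2005 = "numeric",
    dTl = "numeric", dTl_2005 = "numeric", dTg_2005 = "numeric",
    dTg_pi = "numeric", dPr = "numeric", dPr_2005 = "numeric",
    Tave = "numeric", Tave_w = "numeric", Pr_base = "numeric",
    co2_included = "logical", co2_ppm = "numeric",
    adaptation = "logical", adaptation_options = "character",
    imputed_fields = "character", remark = "character")
}

#' Crop, scale and climate-family vocabularies
#' @return Character vector of admissible labels.
#' @export
crop_levels <- function() c("maize", "rice", "soybean", "wheat")

#' @rdname crop_levels
#' @export
scale_levels <- function() {
  c("site", "region", "country_aggregated_grid", "global_grid")
}

#' @rdname crop_levels
#' @export
climate_family_levels <- function() c("CMIP3", "CMIP5", "SRES", "other")

#' Adaptation option taxonomy
#'
#' The seven adaptation categories used to classify management or cultivar
#' changes treated as adaptation by the source studies.
#' @return Character vector of option labels.
#' @export
adaptation_option_levels <- function() {
  c("fertiliser", "irrigation", "cultivar", "planting_time",
    "soil_organic_matter", "tillage", "others")
}

#' Empty corpus with canonical columns
#' @return Zero-row data.frame with the full canonical schema.
#' @export
empty_corpus <- function() {
  sch <- corpus_schema()
  cols <- lapply(sch, function(ty) vector(ty, 0L))
  as.data.frame(cols, stringsAsFactors = FALSE)
}

#' Column mapping between a source layout and the canonical schema
#'
#' Binds deposited spreadsheet headers to canonical fields. The deposited
#' workbook's headers live in a separate metadata workbook, so the binding is
#' configuration, not code.
#'
#' @param columns Named character vector, canonical field -> source header.
#'   The default is the identity mapping over [corpus_schema()].
#' @param na_codes Strings treated as missing on read (never coerced to 0).
#' @param sheets Named list of sheet names for multi-sheet sources.
#' @param required Canonical fields that must resolve for a row to be usable.
#' @return Object of class `column_mapping`.
#' @export
column_mapping <- function(columns = NULL,
                           na_codes = c("", "NA", "n/a"),
                           sheets = list(impacts = "Projected_impacts",
                                         adaptation = "Adaptation_potential",
                                         excluded = "Excluded"),
                           required = c("study_id", "crop", "lat", "lon",
                                        "future_start", "future_end",
                                        "base_start", "base_end")) {
  canon <- names(corpus_schema())
  if (is.null(columns)) {
    columns <- stats::setNames(canon, canon)
  }
  if (is.null(names(columns)) || any(!nzchar(names(columns)))) {
    stop("`columns` must be a named vector (canonical field -> source header)")
  }
  bad <- setdiff(names(columns), canon)
  if (length(bad)) {
    stop("unknown canonical fields in mapping: ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(columns)) {
    dup <- columns[duplicated(columns)]
    stop("two canonical fields map to one source column: ",
         paste(unique(dup), collapse = ", "))
  }
  miss <- setdiff(required, names(columns))
  if (length(miss)) {
    stop("mapping does not cover required fields: ",
         paste(miss, collapse = ", "))
  }
  structure(list(columns = columns, na_codes = na_codes, sheets = sheets,
                 required = required),
            class = "column_mapping")
}

period_midpoint <- function(start, end) {
  # integer midpoint year, half-years rounded down
  as.integer(floor((as.numeric(start) + as.numeric(end)) / 2))
}

coerce_corpus_types <- function(df) {
  sch <- corpus_schema()
  for (nm in names(sch)) {
    if (!nm %in% names(df)) {
      df[[nm]] <- vector(sch[[nm]], nrow(df))
      df[[nm]][] <- NA
    } else {
      df[[nm]] <- switch(sch[[nm]],
        character = as.character(df[[nm]]),
        integer = {
          v <- suppressWarnings(as.numeric(df[[nm]]))
          as.integer(round(v))
        },
        numeric = suppressWarnings(as.numeric(df[[nm]])),
        logical = parse_flag(df[[nm]]))
    }
  }
  # set-valued / free-text fields: empty and absent are the same thing
  for (nm in c("adaptation_options", "imputed_fields", "remark")) {
    df[[nm]][is.na(df[[nm]])] <- ""
  }
  df[names(sch)]
}

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(s))
  out[s %in% c("yes", "y", "true", "1")] <- TRUE
  out[s %in% c("no", "n", "false", "0")] <- FALSE
  out
}

#' Validate records against the schema invariants
#'
#' Checks range, ordering and consistency invariants: latitude/longitude in
#' range, crop within the vocabulary, baseline strictly before the future
#' period with ordered midpoints, yield impact bounded below by -100 when
#' yields are present, the preindustrial/current-baseline warming offset, and
#' that listed adaptation options imply the adaptation flag.
#'
#' @param records Corpus data.frame.
#' @param pi_offset Expected `dTg_pi - dTg_2005` offset in degrees C.
#' @param tol Numeric tolerance for the offset check.
#' @return List with `records` (valid rows) and `rejects` (data.frame of
#'   `row`, `reason`); every input row lands in exactly one of the two.
#' @export
validate_corpus <- function(records, pi_offset = 0.8, tol = 1e-6) {
  n <- nrow(records)
  reason <- character(n)
  add <- function(bad, why) {
    bad <- which(bad)
    reason[bad] <<- ifelse(nzchar(reason[bad]),
                           paste(reason[bad], why, sep = "; "), why)
  }
  ok <- function(x) !is.na(x)
  with(records, {
    add(ok(lat) & (lat < -90 | lat > 90), "lat outside [-90, 90]")
    add(ok(lon) & (lon < -180 | lon > 180), "lon outside [-180, 180]")
    add(ok(crop) & !crop %in% crop_levels(), "crop outside vocabulary")
    add(ok(scale) & !scale %in% scale_levels(), "scale outside vocabulary")
    add(ok(base_start) & ok(base_mid) & base_start > base_mid,
        "base_start > base_mid")
    add(ok(base_mid) & ok(base_end) & base_mid > base_end,
        "base_mid > base_end")
    add(ok(base_end) & ok(future_start) & base_end >= future_start,
        "baseline period overlaps future period")
    add(ok(future_start) & ok(future_mid) & future_start > future_mid,
        "future_start > future_mid")
    add(ok(future_mid) & ok(future_end) & future_mid > future_end,
        "future_mid > future_end")
    add(ok(Yb) & Yb <= 0, "baseline yield not positive")
    add(ok(Yf) & Yf < 0, "future yield negative")
    add(ok(YI_raw) & ok(Yf) & ok(Yb) & Yb > 0 & Yf >= 0 & YI_raw < -100,
        "yield impact below -100% with valid yields")
    add(ok(dTg_pi) & ok(dTg_2005) &
          abs((dTg_pi - dTg_2005) - pi_offset) > tol + 1e-9,
        "preindustrial offset violated")
    add(ok(adaptation_options) & nzchar(adaptation_options) &
          (!ok(adaptation) | !adaptation),
        "adaptation options listed but adaptation flag not set")
    NULL
  })
  bad <- nzchar(reason)
  rejects <- data.frame(row = which(bad), reason = reason[bad],
                        stringsAsFactors = FALSE)
  list(records = records[!bad, , drop = FALSE], rejects = rejects)
}

#' Read a corpus file into canonical records
#'
#' Reads a flat CSV (or, when the file extension is `.xlsx` and \pkg{readxl}
#' is installed, the configured worksheet of a workbook), renames source
#' columns through the mapping, coerces to canonical types, fills period
#' midpoints when absent, and validates. Missing-value codes from the mapping
#' are honoured; blanks are never coerced to zero.
#'
#' @param path Input file (`.csv` or `.xlsx`).
#' @param mapping A [column_mapping()].
#' @param sheet Sheet key (name in `mapping$sheets`) for xlsx input.
#' @param pi_offset Passed to [validate_corpus()].
#' @return List with `records` (valid rows, canonical columns) and `rejects`
#'   (rejection report with row numbers and reasons).
#' @export
read_corpus <- function(path, mapping = column_mapping(), sheet = "impacts",
                        pi_offset = 0.8) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading xlsx requires the readxl package")
    }
    sheet_name <- mapping$sheets[[sheet]]
    if (is.null(sheet_name)) stop("unknown sheet key: ", sheet)
    if (!sheet_name %in% readxl::excel_sheets(path)) {
      stop("sheet not found in workbook: ", sheet_name)
    }
    raw <- as.data.frame(readxl::read_excel(path, sheet = sheet_name,
                                            na = mapping$na_codes))
  } else {
    raw <- utils::read.csv(path, check.names = FALSE,
                           na.strings = mapping$na_codes,
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  }
  absent <- setdiff(unname(mapping$columns[mapping$required]), names(raw))
  if (length(absent)) {
    stop("mapping references absent columns: ", paste(absent, collapse = ", "))
  }
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (canon in names(mapping$columns)) {
    src <- mapping$columns[[canon]]
    if (src %in% names(raw)) out[[canon]] <- raw[[src]]
  }
  out <- coerce_corpus_types(out)
  need_fm <- is.na(out$future_mid) & !is.na(out$future_start) &
    !is.na(out$future_end)
  out$future_mid[need_fm] <-
    period_midpoint(out$future_start[need_fm], out$future_end[need_fm])
  need_bm <- is.na(out$base_mid) & !is.na(out$base_start) & !is.na(out$base_end)
  out$base_mid[need_bm] <-
    period_midpoint(out$base_start[need_bm], out$base_end[need_bm])
  validate_corpus(out, pi_offset = pi_offset)
}

#' Write canonical records to CSV
#'
#' Emits a deterministic column order (the canonical schema order) so two
#' writes of the same records are byte-identical; re-reading reproduces the
#' records field for field. xlsx output is not supported (no xlsx writer in
#' the supported dependency set); multi-sheet corpora are written one CSV per
#' sheet.
#'
#' @param records Corpus data.frame (canonical columns).
#' @param path Output CSV path.
#' @param mapping Optional [column_mapping()] used to rename canonical
#'   columns back to source headers.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(records, path, mapping = NULL) {
  records <- coerce_corpus_types(records)
  out <- records
  if (!is.null(mapping)) {
    keep <- intersect(names(out), names(mapping$columns))
    out <- out[keep]
    names(out) <- unname(mapping$columns[keep])
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Average simulation results over earth-system models
#'
#' Studies driven by several ESMs contribute one projection per ESM for the
#' same crop/site/scenario/period; these are collapsed to their arithmetic
#' mean, mirroring the harmonization step in which results from different
#' ESMs are averaged before analysis.
#'
#' @param records Corpus data.frame.
#' @param group_keys Columns identifying a group; all non-numeric,
#'   non-`esm` columns must agree within a group.
#' @return One record per group with `esm = "ensemble_mean"`; numeric fields
#'   are means over group members (missing values excluded per field).
#' @export
average_over_esms <- function(records,
                              group_keys = c("study_id", "site_label", "crop",
                                             "scenario", "future_mid",
                                             "co2_included", "adaptation")) {
  stopifnot(all(group_keys %in% names(records)))
  dt <- data.table::as.data.table(records)
  sch <- corpus_schema()
  num_cols <- names(sch)[sch %in% c("numeric", "integer")]
  num_cols <- setdiff(intersect(num_cols, names(dt)), group_keys)
  other <- setdiff(names(dt), c(num_cols, group_keys, "esm"))

  check <- dt[, lapply(.SD, function(v) data.table::uniqueN(v, na.rm = FALSE)),
              by = group_keys, .SDcols = other]
  bad <- which(as.matrix(check[, other, with = FALSE]) > 1, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric field(s) disagree within an ESM group: ",
         paste(unique(other[bad[, 2]]), collapse = ", "))
  }

  mean_na <- function(v) {
    m <- mean(v, na.rm = TRUE)
    if (is.nan(m)) NA_real_ else m
  }
  agg_num <- dt[, lapply(.SD, mean_na), by = group_keys, .SDcols = num_cols]
  agg_other <- dt[, .SD[1L], by = group_keys, .SDcols = other]
  agg <- merge(agg_num, agg_other, by = group_keys)
  agg[, esm := "ensemble_mean"]
  out <- as.data.frame(agg)
  coerce_corpus_types(out)
}

#' Restrict grid-aggregated records to top-producing countries
#'
#' Global gridded simulations aggregated to country level are kept only for
#' the smallest set of countries whose cumulative production share reaches
#' `coverage` (default 95% of world production per crop); site and regional
#' records pass through untouched.
#'
#' @param records Corpus data.frame.
#' @param production_table data.frame with `crop`, `country`, `share`
#'   (fraction of world production of that crop).
#' @param coverage Target cumulative share in (0, 1].
#' @return Filtered records.
#' @export
filter_top_producers <- function(records, production_table, coverage = 0.95) {
  stopifnot(all(c("crop", "country", "share") %in% names(production_table)),
            coverage > 0, coverage <= 1)
  gridded <- records$scale %in% c("country_aggregated_grid", "global_grid")
  crops_needed <- unique(records$crop[gridded])
  missing_crops <- setdiff(crops_needed, production_table$crop)
  if (length(missing_crops)) {
    stop("crop absent from production_table: ",
         paste(missing_crops, collapse = ", "))
  }
  keep_tbl <- do.call(rbind, lapply(crops_needed, function(cr) {
    tb <- production_table[production_table$crop == cr, , drop = FALSE]
    tb <- tb[order(-tb$share, tb$country), , drop = FALSE]
    csum <- cumsum(tb$share)
    k <- which(csum >= coverage - 1e-12)[1]
    if (is.na(k)) k <- nrow(tb)
    data.frame(crop = cr, country = tb$country[seq_len(k)],
               stringsAsFactors = FALSE)
  }))
  drop <- gridded & !paste(records$crop, records$country) %in%
    paste(keep_tbl$crop, keep_tbl$country)
  records[!drop, , drop = FALSE]
}
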