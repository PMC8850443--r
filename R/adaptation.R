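#' Default pairing key for adaptation comparisons
#'
#' The finest key available: study, site, crop, scenario, future midpoint and
#' the CO2-fertilization flag. Including the CO2 flag guarantees CO2-on and
#' CO2-off runs never pair.
#' @return Character vector of column names.
#' @export
adaptation_pair_key <- function() {
  c("study_id", "site_label", "crop", "scenario", "future_mid", "co2_included")
}

#' Match with/without-adaptation simulation pairs
#'
#' Within each key group holding exactly one no-adaptation record, every
#' adaptation record is paired with it and the adaptation potential (the
#' percentage-point difference of harmonized impacts) is computed. Groups
#' with several no-adaptation records are reported as ambiguous and not
#' paired; adaptation records with no counterpart are reported unmatched.
#'
#' @param records Harmonized corpus (must carry `YI_2005` and `adaptation`).
#' @param key Columns forming the pairing key.
#' @return List with `pairs` (one row per with/without pair: key columns,
#'   `YI_with`, `YI_without`, `potential`, `options`), `unmatched`
#'   (adaptation records lacking a counterpart) and `ambiguous` (key groups
#'   with multiple no-adaptation records).
#' @export
find_adaptation_pairs <- function(records, key = adaptation_pair_key()) {
  stopifnot(all(key %in% names(records)), "YI_2005" %in% names(records))
  if (!"adaptation" %in% names(records)) stop("records lack adaptation flag")
  dt <- data.table::as.data.table(records)
  dt <- dt[!is.na(dt$adaptation), ]
  dt$.pair_grp <- do.call(paste, c(dt[, key, with = FALSE], sep = "\r"))

  n_without <- dt[, .(nw = sum(!adaptation)), by = ".pair_grp"]
  ambiguous_ids <- n_without$.pair_grp[n_without$nw > 1]
  paired_ids <- n_without$.pair_grp[n_without$nw == 1]

  with_dt <- dt[dt$adaptation == TRUE, ]
  without_dt <- dt[dt$adaptation == FALSE & dt$.pair_grp %in% paired_ids,
                   c(".pair_grp", "YI_2005"), with = FALSE]
  data.table::setnames(without_dt, "YI_2005", "YI_without")

  pairs <- merge(with_dt, without_dt, by = ".pair_grp")
  pairs <- pairs[, c(key, "YI_2005", "YI_without", "adaptation_options"),
                 with = FALSE]
  data.table::setnames(pairs, c("YI_2005", "adaptation_options"),
                       c("YI_with", "options"))
  pairs$potential <- pairs$YI_with - pairs$YI_without

  unmatched <- with_dt[!with_dt$.pair_grp %in% paired_ids, ]
  unmatched$reason <- ifelse(unmatched$.pair_grp %in% ambiguous_ids,
                             "multiple no-adaptation records in group",
                             "no no-adaptation counterpart")
  unmatched <- as.data.frame(unmatched[, c(key, "reason"), with = FALSE])
  ambiguous <- as.data.frame(unique(
    dt[dt$.pair_grp %in% ambiguous_ids, key, with = FALSE]))

  list(pairs = as.data.frame(pairs), unmatched = unmatched,
       ambiguous = ambiguous)
}

#' Adaptation potential of a matched pair
#'
#' The percentage-point difference between the harmonized impact with
#' adaptation and without: `YI_with - YI_without`. Antisymmetric under
#' swapping the two sides.
#'
#' @param YI_with,YI_without Harmonized impacts (percent).
#' @return Percentage points. Vectorized.
#' @export
adaptation_potential <- function(YI_with, YI_without) {
  if (any(is.na(YI_with)) || any(is.na(YI_without))) {
    stop("harmonized impact missing on one side of a pair")
  }
  YI_with - YI_without
}

#' Keep the best-yielding planting-time variant per group
#'
#' When a study tests several planting times, only the variant with the
#' highest future yield is retained (the convention for the planting-time
#' adaptation option). Ties break deterministically to the earliest variant
#' label in sort order.
#'
#' @param records Corpus data.frame carrying a variant label column.
#' @param group_keys Columns within which variants compete.
#' @param variant_col Name of the column labelling planting-time variants.
#' @return Records with one row per group.
#' @export
best_planting_time <- function(records,
                               group_keys = c("study_id", "site_label", "crop",
                                              "scenario", "future_mid",
                                              "co2_included", "adaptation"),
                               variant_col = "planting_variant") {
  stopifnot(all(group_keys %in% names(records)),
            variant_col %in% names(records), "Yf" %in% names(records))
  dt <- data.table::as.data.table(records)
  data.table::setorderv(dt, c(group_keys, variant_col))
  picked <- dt[, .SD[which.max(Yf)], by = group_keys]
  out <- as.data.frame(picked)
  out[, names(records), drop = FALSE]
}
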