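#' Distribution summary of a set of impacts
#'
#' The table of statistics reported for harmonized impacts: n, extremes,
#' mean, quartiles, median, standard deviation, moment-based sample skewness
#' and kurtosis. Skewness is `m3 / m2^(3/2)` and kurtosis `m4 / m2^2`, with
#' the excess convention (normal -> 0) by default; both are flagged
#' undefined (`NA`) for fewer than three values or zero variance. Quantiles
#' use linear interpolation of order statistics (type 7), fixed for
#' reproducibility.
#'
#' @param values Numeric vector (missing values dropped).
#' @param kurtosis_convention `"excess"` (default) or `"raw"`.
#' @param quantile_type Quantile algorithm id (see [stats::quantile()]).
#' @return Object of class `distribution_summary`: a one-row data.frame with
#'   columns `n, min, q1, median, q3, max, mean, sd, skewness, kurtosis,
#'   kurtosis_convention`.
#' @export
distribution_summary <- function(values,
                                 kurtosis_convention = c("excess", "raw"),
                                 quantile_type = 7) {
  kurtosis_convention <- match.arg(kurtosis_convention)
  v <- values[!is.na(values)]
  n <- length(v)
  if (n < 1) stop("empty input")
  m <- mean(v)
  m2 <- mean((v - m)^2)
  skew <- kurt <- NA_real_
  if (n >= 3 && m2 > 0) {
    skew <- mean((v - m)^3) / m2^1.5
    kurt <- mean((v - m)^4) / m2^2
    if (kurtosis_convention == "excess") kurt <- kurt - 3
  }
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = quantile_type,
                       names = FALSE)
  out <- data.frame(n = n, min = min(v), q1 = q[1], median = q[2], q3 = q[3],
                    max = max(v), mean = m,
                    sd = if (n > 1) stats::sd(v) else 0,
                    skewness = skew, kurtosis = kurt,
                    kurtosis_convention = kurtosis_convention,
                    stringsAsFactors = FALSE)
  class(out) <- c("distribution_summary", "data.frame")
  out
}

#' Interquartile-range outlier rule
#'
#' @param anchor `"median"` (default; fences at median +/- multiplier x IQR,
#'   the whisker definition used in the source figures) or `"quartiles"`
#'   (Tukey fences at q1 - multiplier x IQR and q3 + multiplier x IQR).
#' @param multiplier Fence multiplier (default 1.5).
#' @param quantile_type Quantile algorithm id.
#' @return Object of class `outlier_rule`.
#' @export
outlier_rule <- function(anchor = c("median", "quartiles"), multiplier = 1.5,
                         quantile_type = 7) {
  anchor <- match.arg(anchor)
  stopifnot(multiplier > 0)
  structure(list(anchor = anchor, multiplier = multiplier,
                 quantile_type = quantile_type),
            class = "outlier_rule")
}

#' Flag values outside the IQR fences
#'
#' @param values Numeric vector, at least 4 non-missing values.
#' @param rule An [outlier_rule()].
#' @return List with `mask` (logical, `TRUE` = outlier; `NA` input values
#'   give `NA`), `n_removed`, and the numeric `fences`.
#' @export
outlier_mask <- function(values, rule = outlier_rule()) {
  v <- values[!is.na(values)]
  if (length(v) < 4) stop("need at least 4 values for an IQR rule")
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = rule$quantile_type,
                       names = FALSE)
  iqr <- q[3] - q[1]
  fences <- if (rule$anchor == "median") {
    c(q[2] - rule$multiplier * iqr, q[2] + rule$multiplier * iqr)
  } else {
    c(q[1] - rule$multiplier * iqr, q[3] + rule$multiplier * iqr)
  }
  mask <- values < fences[1] | values > fences[2]
  list(mask = mask, n_removed = sum(mask, na.rm = TRUE), fences = fences)
}

#' Outlier-removal sensitivity report
#'
#' Recomputes the mean and median after removing values outside the IQR
#' fences and reports the removed count, the removed percentage, and the
#' shifts of mean and median (after minus before, percentage points for
#' impact inputs). The rule used is echoed in the output.
#'
#' @param values Numeric vector of harmonized impacts.
#' @param rule An [outlier_rule()].
#' @return List: `n`, `n_removed`, `pct_removed`, `mean_before`,
#'   `mean_after`, `delta_mean`, `median_before`, `median_after`,
#'   `delta_median`, `rule`.
#' @export
sensitivity_report <- function(values, rule = outlier_rule()) {
  v <- values[!is.na(values)]
  om <- outlier_mask(v, rule)
  kept <- v[!om$mask]
  list(n = length(v), n_removed = om$n_removed,
       pct_removed = 100 * om$n_removed / length(v),
       mean_before = mean(v), mean_after = mean(kept),
       delta_mean = mean(kept) - mean(v),
       median_before = stats::median(v), median_after = stats::median(kept),
       delta_median = stats::median(kept) - stats::median(v),
       rule = rule)
}

#' Grouped impact summary table
#'
#' One [distribution_summary()] per group x metric, the layout of the
#' per-crop summary tables (per-decade and per-degree impacts without
#' adaptation, harmonized impacts by region or scenario, adaptation
#' potentials). Records whose per-degree value is flagged undefined are
#' excluded from the `per_degree` metric (and only from it); the exclusion
#' count is carried in the output.
#'
#' @param records Harmonized corpus data.frame.
#' @param group_keys Record fields to group by.
#' @param metrics Column names to summarize, subset of
#'   `c("YI_2005", "per_decade", "per_degree", "potential")`.
#' @param kurtosis_convention Passed to [distribution_summary()].
#' @return data.frame with the group keys, `metric`, the summary columns,
#'   and attribute `"n_excluded_undefined"` (per-degree flag exclusions).
#' @export
grouped_impact_table <- function(records, group_keys = "crop",
                                 metrics = c("per_decade", "per_degree"),
                                 kurtosis_convention = "excess") {
  bad_keys <- setdiff(group_keys, names(records))
  if (length(bad_keys)) stop("unknown group key: ",
                             paste(bad_keys, collapse = ", "))
  allowed <- c("YI_2005", "per_decade", "per_degree", "potential")
  bad_m <- setdiff(metrics, allowed)
  if (length(bad_m)) stop("unknown metric: ", paste(bad_m, collapse = ", "))
  miss_m <- setdiff(metrics, names(records))
  if (length(miss_m)) stop("metric column absent: ",
                           paste(miss_m, collapse = ", "))

  n_excl <- 0L
  groups <- split(seq_len(nrow(records)),
                  records[group_keys], drop = TRUE, sep = "\r")
  rows <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    keyvals <- records[idx[1], group_keys, drop = FALSE]
    for (met in metrics) {
      v <- records[[met]][idx]
      if (met == "per_degree" && "per_degree_defined" %in% names(records)) {
        def <- records$per_degree_defined[idx]
        n_excl <- n_excl + sum(!def, na.rm = TRUE)
        v <- v[def %in% TRUE]
      }
      v <- v[!is.na(v)]
      if (!length(v)) next
      s <- distribution_summary(v, kurtosis_convention = kurtosis_convention)
      rows[[length(rows) + 1L]] <-
        cbind(keyvals, metric = met, as.data.frame(s), row.names = NULL)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    cbind(records[0, group_keys, drop = FALSE], metric = character(0))
  attr(out, "n_excluded_undefined") <- n_excl
  out
}

#' Assign mid-century / end-century period bins
#'
#' @param future_mid Future midpoint years.
#' @param mc_range Years binned as mid-century (default 2040-2069).
#' @param ec_start First end-century year (default 2070).
#' @return Character vector: `"NF"` (near future), `"MC"`, `"EC"`.
#' @export
period_bin <- function(future_mid, mc_range = c(2040, 2069), ec_start = 2070) {
  out <- rep(NA_character_, length(future_mid))
  ok <- !is.na(future_mid)
  out[ok & future_mid < mc_range[1]] <- "NF"
  out[ok & future_mid >= mc_range[1] & future_mid <= mc_range[2]] <- "MC"
  out[ok & future_mid >= ec_start] <- "EC"
  out
}
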