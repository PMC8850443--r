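#' Harmonization configuration
#'
#' @param ref_mid_year Reference baseline-period midpoint year that all
#'   effect sizes are rescaled to (the 2001-2010 window, midpoint 2005).
#' @param counterfactual_mode `"corrected"` (default; identical technological
#'   trends cancel to zero impact) or `"literal"` (the formula exactly as
#'   printed, retained for audit).
#' @param per_degree_basis Warming denominator for per-degree impacts:
#'   `"dTg_2005"` (global-mean rise from 2001-2010, default) or `"dTl_2005"`
#'   (local rise).
#' @param min_degree_denominator Warming magnitudes below this (degrees C) are
#'   flagged undefined rather than divided, to avoid exploding ratios.
#' @param min_year_gap Minimum study year gap (years) for any time rescaling.
#' @return Object of class `impact_config`.
#' @export
impact_config <- function(ref_mid_year = 2005,
                          counterfactual_mode = c("corrected", "literal"),
                          per_degree_basis = c("dTg_2005", "dTl_2005"),
                          min_degree_denominator = 0.1,
                          min_year_gap = 1) {
  counterfactual_mode <- match.arg(counterfactual_mode)
  per_degree_basis <- match.arg(per_degree_basis)
  stopifnot(min_degree_denominator > 0, min_year_gap > 0)
  structure(list(ref_mid_year = ref_mid_year,
                 counterfactual_mode = counterfactual_mode,
                 per_degree_basis = per_degree_basis,
                 min_degree_denominator = min_degree_denominator,
                 min_year_gap = min_year_gap),
            class = "impact_config")
}

#' Relative yield impact (percent)
#'
#' The core effect size: percent change of projected future yield relative to
#' the study's baseline-period yield, `(Yf/Yb - 1) * 100`. Bounded below by
#' -100 for non-negative future yields.
#'
#' @param Yf Future yield, t/ha (>= 0).
#' @param Yb Baseline yield, t/ha (> 0).
#' @return Impact in percent. Vectorized.
#' @export
relative_yield_impact <- function(Yf, Yb) {
  if (any(!is.na(Yb) & Yb <= 0)) stop("baseline yield must be positive")
  if (any(!is.na(Yf) & Yf < 0)) stop("future yield must be non-negative")
  (Yf / Yb - 1) * 100
}

#' Counterfactual yield impact (percent)
#'
#' For studies simulating both a climate-change run and a counterfactual
#' no-climate-change run (so that technological yield trends can be
#' subtracted), the impact is the difference of the two yield trends relative
#' to the climate-change baseline. `mode = "literal"` reproduces the formula
#' as printed, whose trailing `- 1` makes identical trends score -100%;
#' `mode = "corrected"` (default) drops that term so equal trends give zero.
#'
#' @param Yf_cc,Yb_cc Future and baseline mean yields with climate change.
#' @param Yf_ncc,Yb_ncc The same under the no-climate-change counterfactual.
#' @param mode `"corrected"` or `"literal"`.
#' @return Impact in percent, with the producing mode in attribute `"mode"`.
#' @export
counterfactual_yield_impact <- function(Yf_cc, Yb_cc, Yf_ncc, Yb_ncc,
                                        mode = c("corrected", "literal")) {
  mode <- match.arg(mode)
  if (any(!is.na(Yb_cc) & Yb_cc <= 0)) {
    stop("climate-change baseline yield must be positive")
  }
  core <- ((Yf_cc - Yb_cc) - (Yf_ncc - Yb_ncc)) / Yb_cc
  out <- if (mode == "literal") (core - 1) * 100 else core * 100
  attr(out, "mode") <- mode
  out
}

#' Rescale an effect size to the reference baseline midpoint
#'
#' Baseline periods differ between studies. An impact (or temperature or
#' precipitation change) is first divided by the study's year gap
#' (future midpoint - study baseline midpoint), giving a per-year rate, then
#' multiplied by the gap from the reference midpoint (2005 by default):
#' `value * (future_mid - ref_mid) / (future_mid - base_mid)`. Identity when
#' the study baseline midpoint already equals the reference.
#'
#' @param value Effect size (percent, degrees C, or mm).
#' @param future_mid,base_mid Study future and baseline midpoint years.
#' @param ref_mid Reference midpoint year.
#' @param min_year_gap Minimum admissible `future_mid - base_mid`.
#' @return Rescaled value, same units. Vectorized.
#' @export
baseline_correct <- function(value, future_mid, base_mid, ref_mid = 2005,
                             min_year_gap = 1) {
  gap <- future_mid - base_mid
  if (any(!is.na(gap) & gap < min_year_gap)) {
    stop("study year gap below minimum (", min_year_gap, " year)")
  }
  value * (future_mid - ref_mid) / gap
}

#' Per-decade yield impact
#'
#' Harmonized impact divided by decades elapsed since the reference midpoint:
#' `YI_2005 / (future_mid - ref_mid) * 10`.
#'
#' @param YI_2005 Baseline-corrected impact, percent.
#' @param future_mid Future midpoint year.
#' @param ref_mid Reference midpoint year.
#' @param min_year_gap Minimum admissible year gap.
#' @return Percent per decade. Vectorized.
#' @export
per_decade_impact <- function(YI_2005, future_mid, ref_mid = 2005,
                              min_year_gap = 1) {
  gap <- future_mid - ref_mid
  if (any(!is.na(gap) & gap < min_year_gap)) {
    stop("year gap from reference midpoint below minimum")
  }
  YI_2005 / gap * 10
}

#' Per-warming-degree yield impact
#'
#' Harmonized impact divided by degrees of warming. Warming magnitudes below
#' `min_degree` are not divided: the result is `NA` with the companion
#' `defined` flag `FALSE`, and such rows are excluded from summaries rather
#' than contributing zeros or exploding ratios.
#'
#' @param YI_2005 Baseline-corrected impact, percent.
#' @param warming Warming in degrees C (global or local; see
#'   [impact_config()]'s `per_degree_basis`).
#' @param min_degree Threshold below which the ratio is undefined.
#' @param basis Label recorded in the output attribute.
#' @return Numeric vector (percent per degree C) with attribute `"basis"` and
#'   attribute `"defined"` (logical vector).
#' @export
per_degree_impact <- function(YI_2005, warming, min_degree = 0.1,
                              basis = "dTg_2005") {
  defined <- !is.na(warming) & abs(warming) >= min_degree
  out <- ifelse(defined & !is.na(YI_2005), YI_2005 / warming, NA_real_)
  attr(out, "basis") <- basis
  attr(out, "defined") <- defined
  out
}

#' Harmonize a corpus: effect sizes, baseline correction, rates
#'
#' Computes, per record: `YI_raw` from yields where absent, `YI_2005`,
#' `dTl_2005` and `dPr_2005` by baseline correction, and the
#' `per_decade` / `per_degree` normalizations (with `per_degree_defined`
#' flag and the warming basis stamped in the `per_degree_basis` column).
#' Records whose year gap is degenerate keep `NA` harmonized values.
#'
#' @param records Corpus data.frame (canonical columns).
#' @param config An [impact_config()].
#' @return The records with harmonized columns added/updated.
#' @export
harmonize_records <- function(records, config = impact_config()) {
  r <- records
  need_yi <- is.na(r$YI_raw) & !is.na(r$Yf) & !is.na(r$Yb) & r$Yb > 0
  r$YI_raw[need_yi] <- relative_yield_impact(r$Yf[need_yi], r$Yb[need_yi])

  gap <- r$future_mid - r$base_mid
  usable <- !is.na(gap) & gap >= config$min_year_gap
  corr <- function(v) {
    out <- rep(NA_real_, nrow(r))
    i <- usable & !is.na(v)
    out[i] <- baseline_correct(v[i], r$future_mid[i], r$base_mid[i],
                               config$ref_mid_year, config$min_year_gap)
    out
  }
  r$YI_2005 <- corr(r$YI_raw)
  r$dTl_2005 <- ifelse(is.na(r$dTl_2005), corr(r$dTl), r$dTl_2005)
  r$dPr_2005 <- ifelse(is.na(r$dPr_2005), corr(r$dPr), r$dPr_2005)

  ref_gap <- r$future_mid - config$ref_mid_year
  ok_dec <- !is.na(ref_gap) & ref_gap >= config$min_year_gap & !is.na(r$YI_2005)
  r$per_decade <- NA_real_
  r$per_decade[ok_dec] <- per_decade_impact(r$YI_2005[ok_dec],
                                            r$future_mid[ok_dec],
                                            config$ref_mid_year,
                                            config$min_year_gap)

  warming <- r[[config$per_degree_basis]]
  pdg <- per_degree_impact(r$YI_2005, warming,
                           config$min_degree_denominator,
                           basis = config$per_degree_basis)
  r$per_degree <- as.numeric(pdg)
  r$per_degree_defined <- attr(pdg, "defined") & !is.na(r$YI_2005)
  r$per_degree_basis <- config$per_degree_basis
  r
}
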