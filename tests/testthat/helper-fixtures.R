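# minimal canonical record builder; override any column via ...
rec <- function(n = 1, ...) {
  base <- data.frame(
    study_id = "S1", ref_label = "S1_ref", pub_year = 2015L, crop = "maize",
    country = "France", site_label = "site1", lat = 45, lon = 2,
    scale = "site", region_group = "Europe", climate_family = "CMIP5",
    scenario = "RCP8.5", esm = "ensemble_mean",
    future_start = 2041L, future_end = 2060L, future_mid = 2050L,
    base_start = 1995L, base_end = 2014L, base_mid = 2004L,
    Yb = 5, Yf = 4.5, YI_raw = NA_real_, YI_2005 = NA_real_,
    dTl = 2, dTl_2005 = NA_real_, dTg_2005 = 2.2, dTg_pi = 3.0,
    dPr = 10, dPr_2005 = NA_real_, Tave = 12, Tave_w = 12.5, Pr_base = 800,
    co2_included = TRUE, co2_ppm = 540, adaptation = FALSE,
    adaptation_options = "", imputed_fields = "", remark = "",
    stringsAsFactors = FALSE)
  out <- base[rep(1, n), , drop = FALSE]
  row.names(out) <- NULL
  args <- list(...)
  for (nm in names(args)) out[[nm]] <- args[[nm]]
  out
}

# small half-degree grid helper: values matrix over given centers
toy_grid <- function(values, lats = c(44.75, 45.25), lons = c(1.75, 2.25),
                     variable = "annual_mean_temp_C") {
  climate_grid(matrix(values, length(lats), length(lons)),
               lats, lons, variable = variable)
}

# independent type-7 quantile: linear interpolation of order statistics,
# h = (n - 1) p + 1, written from the formula (oracle for outlier fences)
quantile7_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# brute-force fence computation for both anchor conventions
outlier_oracle <- function(v, anchor, mult = 1.5) {
  q1 <- quantile7_oracle(v, 0.25)
  q2 <- quantile7_oracle(v, 0.50)
  q3 <- quantile7_oracle(v, 0.75)
  iqr <- q3 - q1
  f <- if (anchor == "median") c(q2 - mult * iqr, q2 + mult * iqr)
       else c(q1 - mult * iqr, q3 + mult * iqr)
  v < f[1] | v > f[2]
}
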