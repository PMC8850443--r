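#' Configuration of the synthetic-corpus generator
#'
#' Defaults describe the composition of the consolidated real corpus: crop
#' shares (maize about half the simulations, soybean rare), climate-scenario
#' families (80% CMIP5, 11% CMIP3), a 61% adaptation share, roughly half of
#' local temperature rises unreported, matched with/without-adaptation pairs
#' for 23% of simulations, heterogeneous baseline periods with midpoints in
#' 1961-2005, and future midpoints clustered at 2020/2050/2080. The yield
#' response surface is
#' `YI = b0 + b1 * dTl * max(0, Tave - T_crit) + b2 * log(ppm/370) * co2 +
#' b3 * adaptation + crop_effect + skewed noise`, with left-skewed noise so
#' the generated impact distribution has negative skewness.
#'
#' Crop shares are the printed rounded percentages and sum to 0.98; they are
#' renormalized proportionally here so proportions sum to one.
#'
#' @param n_records Number of simulation records to emit.
#' @param n_studies Number of synthetic studies (default about one study per
#'   43 records, the corpus-wide average).
#' @param crop_proportions,scenario_mix Named shares (renormalized).
#' @param adaptation_fraction Share of records with adaptation.
#' @param pair_fraction Matched with/without pairs per record (pairs / n).
#' @param dTl_missing_rate Share of records whose local temperature rise is
#'   masked missing.
#' @param response_coefficients Named vector `b0, b1, b2, b3` of the yield
#'   response surface (percent scale).
#' @param crop_effects Named additive crop effects (percentage points).
#' @param T_crit Temperature threshold (degrees C) above which warming hurts.
#' @param noise_sd Yield-impact noise standard deviation, percent.
#' @param skew_parameter Skew-normal shape; negative for left skew.
#' @param temp_noise_sd Local-warming noise around its smooth surface,
#'   degrees C.
#' @param grid_share Share of records flagged as country-aggregated grid
#'   output.
#' @param co2_off_rate Share of simulations run without CO2 fertilization.
#' @param seed Integer seed; the corpus is reproducible from it.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_records = 5000,
                             n_studies = NULL,
                             crop_proportions = c(maize = 0.52, wheat = 0.26,
                                                  rice = 0.17, soybean = 0.03),
                             scenario_mix = c(CMIP5 = 0.80, CMIP3 = 0.11,
                                              other = 0.09),
                             adaptation_fraction = 0.61,
                             pair_fraction = 0.23,
                             dTl_missing_rate = 0.50,
                             response_coefficients = c(b0 = 3, b1 = -0.5,
                                                       b2 = 8, b3 = 9),
                             crop_effects = c(maize = -6, rice = 0,
                                              soybean = -3, wheat = -2),
                             T_crit = 12,
                             noise_sd = 15,
                             skew_parameter = -4,
                             temp_noise_sd = 0.1,
                             grid_share = 0.15,
                             co2_off_rate = 0.05,
                             seed = 42) {
  stopifnot(n_records >= 1, all(crop_proportions > 0), all(scenario_mix > 0))
  rates <- c(adaptation_fraction, pair_fraction, dTl_missing_rate,
             grid_share, co2_off_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (noise_sd < 0 || temp_noise_sd < 0) stop("noise sds must be >= 0")
  crop_proportions <- crop_proportions / sum(crop_proportions)
  scenario_mix <- scenario_mix / sum(scenario_mix)
  if (abs(sum(crop_proportions) - 1) > 1e-9 ||
      abs(sum(scenario_mix) - 1) > 1e-9) stop("proportions must sum to 1")
  if (is.null(n_studies)) n_studies <- max(1L, ceiling(n_records / 43))
  stopifnot(all(c("b0", "b1", "b2", "b3") %in% names(response_coefficients)),
            all(names(crop_effects) %in% crop_levels()))
  structure(list(n_records = n_records, n_studies = n_studies,
                 crop_proportions = crop_proportions,
                 scenario_mix = scenario_mix,
                 adaptation_fraction = adaptation_fraction,
                 pair_fraction = pair_fraction,
                 dTl_missing_rate = dTl_missing_rate,
                 response_coefficients = response_coefficients,
                 crop_effects = crop_effects, T_crit = T_crit,
                 noise_sd = noise_sd, skew_parameter = skew_parameter,
                 temp_noise_sd = temp_noise_sd, grid_share = grid_share,
                 co2_off_rate = co2_off_rate, seed = seed),
            class = "generator_config")
}

#' Country/region lookup used for synthetic site placement
#'
#' Representative producer countries with an IPCC-style region label and a
#' central coordinate; a synthetic lookup fixture, not an official region
#' polygon product.
#' @return data.frame with `country`, `region_group`, `lat`, `lon`.
#' @export
region_lookup <- function() {
  utils::read.csv(system.file("extdata", "region_lookup.csv",
                              package = "cropclim"),
                  stringsAsFactors = FALSE)
}

# standardized skew-normal deviates: mean 0, sd 1, left-skewed for alpha < 0
rskewnorm_std <- function(n, alpha) {
  delta <- alpha / sqrt(1 + alpha^2)
  z <- delta * abs(stats::rnorm(n)) + sqrt(1 - delta^2) * stats::rnorm(n)
  mu <- delta * sqrt(2 / pi)
  (z - mu) / sqrt(1 - 2 * delta^2 / pi)
}

scenario_for_family <- function(family, n) {
  switch(family,
    CMIP5 = sample(c("RCP2.6", "RCP4.5", "RCP8.5"), n, replace = TRUE),
    CMIP3 = sample(c("A2", "A1B", "B1"), n, replace = TRUE),
    rep("other", n))
}

warming_rate <- function(scenario) {
  rates <- c("RCP2.6" = 0.018, "RCP4.5" = 0.030, "RCP8.5" = 0.050,
             "A2" = 0.045, "A1B" = 0.035, "B1" = 0.022, "other" = 0.030)
  unname(rates[scenario])
}

#' Generate a synthetic yield-projection corpus with ground truth
#'
#' Draws simulation units (site, crop, scenario, periods), builds the local
#' warming from the global rise via a smooth latitude response
#' `dTl = dTg * (1 + 0.5 cos(2 pi lat / 180)) + noise`, evaluates the yield
#' response surface on the reference-baseline scale, adds left-skewed noise,
#' and back-transforms to study-scale raw impacts and yields (floored at
#' -100%, i.e. zero future yield). A `pair_fraction` share of units is
#' emitted as matched with/without-adaptation pairs sharing every pairing-key
#' field; local warming is masked missing at `dTl_missing_rate`.
#'
#' @param config A [generator_config()].
#' @return List with `records` (canonical corpus, see [corpus_schema()]) and
#'   `truth` (coefficients, per-record noiseless `YI_2005_true` and
#'   `dTl_2005_true`, pair membership, seed).
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(config) {
  n <- config$n_records
  n_pairs <- round(config$pair_fraction * n / 2) # pairs emit 2 records each
  n_singles <- n - 2 * n_pairs
  n_units <- n_pairs + n_singles
  cf <- config$response_coefficients

  look <- region_lookup()
  co2_tab <- co2_trajectories()

  # unit-level draws -------------------------------------------------------
  site_row <- sample(nrow(look), n_units, replace = TRUE)
  lat <- pmin(83, pmax(-56, look$lat[site_row] + stats::runif(n_units, -4, 4)))
  lon <- pmin(180, pmax(-180, look$lon[site_row] +
                          stats::runif(n_units, -6, 6)))
  crop <- sample(names(config$crop_proportions), n_units, replace = TRUE,
                 prob = config$crop_proportions)
  family <- sample(names(config$scenario_mix), n_units, replace = TRUE,
                   prob = config$scenario_mix)
  scenario <- character(n_units)
  for (fam in unique(family)) {
    i <- family == fam
    scenario[i] <- scenario_for_family(fam, sum(i))
  }
  study <- sprintf("S%03d", sample(config$n_studies, n_units, replace = TRUE))

  future_mid <- sample(c(2020L, 2050L, 2080L), n_units, replace = TRUE,
                       prob = c(0.25, 0.40, 0.35))
  future_start <- future_mid - 9L
  future_end <- future_mid + 10L
  base_start <- sample(1961:1986, n_units, replace = TRUE)
  base_end <- pmin(base_start + sample(c(9L, 19L, 29L), n_units,
                                       replace = TRUE), 2010L)
  base_mid <- period_midpoint(base_start, base_end)

  dTg_2005 <- warming_rate(scenario) * (future_mid - 2005) *
    stats::runif(n_units, 0.85, 1.15)
  dTg_pi <- dTg_2005 + 0.8
  dTl_2005_true <- dTg_2005 * (1 + 0.5 * cos(2 * pi * lat / 180))
  dTl_2005_obs <- dTl_2005_true +
    stats::rnorm(n_units, 0, config$temp_noise_sd)

  Tave <- pmin(30, pmax(-5, 27 - 0.4 * abs(lat) + stats::rnorm(n_units, 0, 1.5)))
  Tave_w <- Tave + stats::rnorm(n_units, 0, 0.7)
  Pr_base <- pmin(3000, pmax(100, exp(stats::rnorm(n_units, log(800), 0.45))))
  rel_pr <- stats::rnorm(n_units, 0, 6) * (1 + 0.3 * dTg_2005)
  dPr_2005 <- precip_change_from_relative(rel_pr, Pr_base)

  co2_included <- stats::runif(n_units) > config$co2_off_rate
  co2_ppm <- rep(370, n_units)
  for (sc in unique(scenario)) {
    i <- which(scenario == sc & co2_included)
    traj <- co2_tab[[sc]]
    if (is.null(traj)) traj <- co2_tab[["other"]]
    if (length(i)) co2_ppm[i] <- co2_concentration(traj, future_mid[i])
  }

  scale <- ifelse(stats::runif(n_units) < config$grid_share,
                  "country_aggregated_grid", "site")

  # expand pair units into with/without rows --------------------------------
  is_pair_unit <- seq_len(n_units) <= n_pairs
  q_single <- (config$adaptation_fraction * n - n_pairs) / max(n_singles, 1)
  q_single <- min(max(q_single, 0), 1)
  adapt_single <- stats::runif(n_singles) < q_single

  unit_of <- c(which(is_pair_unit), which(is_pair_unit), which(!is_pair_unit))
  adaptation <- c(rep(FALSE, n_pairs), rep(TRUE, n_pairs), adapt_single)
  n_rec <- length(unit_of)

  surface <- cf[["b0"]] +
    cf[["b1"]] * dTl_2005_obs[unit_of] *
      pmax(0, Tave[unit_of] - config$T_crit) +
    cf[["b2"]] * log(co2_ppm[unit_of] / 370) * co2_included[unit_of] +
    unname(config$crop_effects[crop[unit_of]]) +
    cf[["b3"]] * adaptation
  eps <- if (config$noise_sd > 0) {
    config$noise_sd * rskewnorm_std(n_rec, config$skew_parameter)
  } else rep(0, n_rec)

  gap_ratio <- (future_mid[unit_of] - base_mid[unit_of]) /
    (future_mid[unit_of] - 2005)
  YI_raw <- pmax(-100, (surface + eps) * gap_ratio)
  Yb <- exp(stats::rnorm(n_rec, log(4), 0.35))
  Yf <- Yb * (1 + YI_raw / 100)

  dTl_raw <- dTl_2005_obs[unit_of] * gap_ratio
  dTl_missing <- stats::runif(n_rec) < config$dTl_missing_rate
  dTl_raw[dTl_missing] <- NA_real_
  dPr_raw <- dPr_2005[unit_of] * gap_ratio

  opts <- adaptation_option_levels()
  opt_w <- c(fertiliser = 0.32, irrigation = 0.29, cultivar = 0.17,
             planting_time = 0.17, soil_organic_matter = 0.02,
             tillage = 0.01, others = 0.02)
  pick_opts <- function(k) {
    paste(sort(sample(opts, k, prob = opt_w[opts])), collapse = ",")
  }
  n_opts <- ifelse(adaptation, 1L + (stats::runif(n_rec) < 0.5), 0L)
  adaptation_options <- character(n_rec)
  adaptation_options[adaptation] <-
    vapply(n_opts[adaptation], pick_opts, "")

  study_num <- as.integer(sub("S", "", study[unit_of]))
  records <- data.frame(
    study_id = study[unit_of],
    ref_label = paste0(study[unit_of], "_ref"),
    pub_year = 1990L + study_num %% 31L,
    crop = crop[unit_of],
    country = look$country[site_row[unit_of]],
    site_label = sprintf("site_%04d", unit_of),
    lat = lat[unit_of], lon = lon[unit_of],
    scale = scale[unit_of],
    region_group = look$region_group[site_row[unit_of]],
    climate_family = family[unit_of],
    scenario = scenario[unit_of],
    esm = "ensemble_mean",
    future_start = future_start[unit_of], future_end = future_end[unit_of],
    future_mid = future_mid[unit_of],
    base_start = base_start[unit_of], base_end = base_end[unit_of],
    base_mid = base_mid[unit_of],
    Yb = Yb, Yf = Yf, YI_raw = YI_raw, YI_2005 = NA_real_,
    dTl = dTl_raw, dTl_2005 = NA_real_,
    dTg_2005 = dTg_2005[unit_of], dTg_pi = dTg_pi[unit_of],
    dPr = dPr_raw, dPr_2005 = NA_real_,
    Tave = Tave[unit_of], Tave_w = Tave_w[unit_of],
    Pr_base = Pr_base[unit_of],
    co2_included = co2_included[unit_of], co2_ppm = co2_ppm[unit_of],
    adaptation = adaptation,
    adaptation_options = adaptation_options,
    imputed_fields = "", remark = "",
    stringsAsFactors = FALSE)
  records <- coerce_corpus_types(records)

  truth <- list(
    coefficients = cf,
    crop_effects = config$crop_effects,
    T_crit = config$T_crit,
    noise_sd = config$noise_sd,
    temp_noise_sd = config$temp_noise_sd,
    dTl_2005_true = dTl_2005_true[unit_of],
    dTl_2005_obs = dTl_2005_obs[unit_of],
    YI_2005_true = surface,
    unit = unit_of,
    is_pair_member = c(rep(TRUE, 2 * n_pairs), rep(FALSE, n_singles)),
    n_pairs = n_pairs,
    seed = config$seed)
  list(records = records, truth = truth)
}

#' End-to-end recovery report on a synthetic corpus
#'
#' Runs the full pipeline (harmonize, impute the local warming, pair,
#' summarize) on a generated corpus and compares each stage against the
#' generator's ground truth: imputation RMSE versus the known noise floor,
#' mean recovered adaptation potential versus `b3`, and the sign of the
#' median per-degree impact in the warm stratum versus the sign of the
#' warming coefficient.
#'
#' @param records,truth Output of [generate_corpus()].
#' @param folds,num_trees,seed Imputation settings (trees reduced from the
#'   500 default for runtime; selection logic unchanged).
#' @return List of recovery diagnostics.
#' @export
recovery_suite <- function(records, truth, folds = 5, num_trees = 100,
                           seed = 1) {
  h <- harmonize_records(records)
  masked <- is.na(h$dTl_2005)
  fit <- fit_imputer(h, "dTl_2005", folds = folds, seed = seed,
                     num_trees = num_trees)
  imp <- impute_missing(h, fit$model)
  h2 <- imp$records
  rmse_imputed <- sqrt(mean(
    (h2$dTl_2005[masked] - truth$dTl_2005_obs[masked])^2))

  pr <- find_adaptation_pairs(h2)
  mean_potential <- if (nrow(pr$pairs)) mean(pr$pairs$potential) else NA_real_

  warm <- h2$Tave > 20 & h2$per_degree_defined %in% TRUE
  med_per_degree_warm <- stats::median(h2$per_degree[warm], na.rm = TRUE)

  list(imputation_report = fit$report,
       imputation_rmse = rmse_imputed,
       noise_floor = truth$temp_noise_sd,
       n_imputed = imp$n_imputed,
       mean_potential = mean_potential,
       n_pairs = nrow(pr$pairs),
       b3 = unname(truth$coefficients[["b3"]]),
       median_per_degree_warm = med_per_degree_warm,
       b1_sign = sign(unname(truth$coefficients[["b1"]])))
}
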