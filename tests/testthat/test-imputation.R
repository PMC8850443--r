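# trees scaled below the 500-tree default throughout for runtime; the
# selection logic and contracts under test are tree-count independent

test_that("forest regressor fits, predicts and is deterministic", {
  set.seed(1)
  n <- 400
  x <- cbind(a = runif(n), b = runif(n))
  y <- 3 * x[, "a"] + rnorm(n, 0, 0.05)
  f1 <- crop_rf(x, y, num_trees = 50, seed = 9)
  f2 <- crop_rf(x, y, num_trees = 50, seed = 9)
  expect_identical(predict(f1, x), predict(f2, x))
  expect_gt(f1$oob_r2, 0.9)
  expect_lt(sqrt(mean((predict(f1, x) - y)^2)), 0.2)
  expect_error(crop_rf(cbind(x, c = NA), y), "missing values")
})

test_that("candidate bookkeeping: errors, constant target, determinism", {
  g <- generate_corpus(generator_config(n_records = 400, seed = 3))
  h <- harmonize_records(g$records)
  expect_error(fit_imputer(h, "dTl_2005",
                           candidates = list(c("dTg_2005", "no_such_col")),
                           num_trees = 10),
               "unknown feature")
  expect_error(fit_imputer(h[1:20, ], "dTl_2005", num_trees = 10),
               "too few")
  expect_error(default_candidates("xyz"), "unknown imputation target")
  expect_true(all(c("dTg_2005", "lat", "lon") %in%
                    default_candidates("dTl_2005")$reduced3))
  expect_true("Pr_base" %in% default_candidates("dPr")$best7)

  # constant target: CV RMSE collapses to zero
  hc <- h
  hc$dTl_2005 <- 1.7
  fitc <- fit_imputer(hc, "dTl_2005",
                      candidates = list(r3 = c("dTg_2005", "lat", "lon")),
                      folds = 4, num_trees = 20)
  expect_lte(fitc$report$candidates$cv_rmse, 1e-6)

  # same seed, same report
  f1 <- fit_imputer(h, "dTl_2005",
                    candidates = default_candidates("dTl_2005")[c(1, 4)],
                    folds = 4, num_trees = 20, seed = 5)
  f2 <- fit_imputer(h, "dTl_2005",
                    candidates = default_candidates("dTl_2005")[c(1, 4)],
                    folds = 4, num_trees = 20, seed = 5)
  expect_identical(f1$report$candidates, f2$report$candidates)
})

test_that("imputation fills only missing values and never alters observed ones", {
  g <- generate_corpus(generator_config(n_records = 800, seed = 13))
  h <- harmonize_records(g$records)
  fit <- fit_imputer(h, "dTl_2005",
                     candidates = list(r3 = c("dTg_2005", "lat", "lon")),
                     folds = 4, num_trees = 40, seed = 2)
  before <- h$dTl_2005
  res <- impute_missing(h, fit$model)
  after <- res$records$dTl_2005
  obs <- !is.na(before)
  expect_identical(after[obs], before[obs]) # bitwise untouched
  expect_equal(res$n_imputed, sum(is.na(before)))
  expect_false(anyNA(after))
  expect_true(all(grepl("dTl_2005",
                        res$records$imputed_fields[is.na(before)])))
  # untouched rows: full record equality
  expect_identical(res$records[obs, setdiff(names(h), "imputed_fields")],
                   h[obs, setdiff(names(h), "imputed_fields")])

  # no missing values -> identity
  res2 <- impute_missing(res$records, fit$model)
  expect_identical(res2$records, res$records)
  expect_equal(res2$n_imputed, 0)

  # a row missing a model feature is skipped and reported
  h3 <- h
  h3$dTg_2005[which(is.na(h3$dTl_2005))[1]] <- NA
  res3 <- impute_missing(h3, fit$model)
  expect_equal(res3$skipped, which(is.na(h3$dTl_2005) & is.na(h3$dTg_2005)))
  expect_true(is.na(res3$records$dTl_2005[res3$skipped]))

  expect_error(impute_missing(h, fit$model, target = "dPr"), "fitted for")
})

test_that("adding a pure-noise feature to the winning set barely moves CV RMSE", {
  g <- generate_corpus(generator_config(n_records = 2000, seed = 17))
  h <- harmonize_records(g$records)
  h$pure_noise <- with_seed(7, rnorm(nrow(h)))
  fit <- fit_imputer(h, "dTl_2005",
                     candidates = list(win = c("dTg_2005", "lat", "lon"),
                                       noisy = c("dTg_2005", "lat", "lon",
                                                 "pure_noise")),
                     folds = 5, num_trees = 60, seed = 21)
  rmse <- fit$report$candidates$cv_rmse
  expect_lt(abs(rmse[2] - rmse[1]) / rmse[1], 0.20)
})

test_that("parameter recovery: selected-model CV RMSE sits on the noise floor", {
  # smaller-n analogue of the full recovery criterion (runtime)
  g <- generate_corpus(generator_config(n_records = 3000, seed = 29))
  h <- harmonize_records(g$records)
  fit <- fit_imputer(h, "dTl_2005", folds = 5, num_trees = 80, seed = 3)
  sigma <- 0.1
  rmse <- min(fit$report$candidates$cv_rmse)
  expect_gte(rmse, sigma)
  expect_lte(rmse, 2.5 * sigma)
})

test_that("multi-target wrapper imputes in dependency order", {
  g <- generate_corpus(generator_config(n_records = 600, seed = 41))
  h <- harmonize_records(g$records)
  # knock out some global rises too
  drop <- with_seed(4, sample(nrow(h), 60))
  h$dTg_2005[drop] <- NA
  out <- impute_climate_covariates(h, targets = c("dTg_2005", "dTl_2005"),
                                   folds = 3, num_trees = 30, seed = 8)
  expect_named(out$reports, c("dTg_2005", "dTl_2005"))
  # dTg rows with the dTl feature observed get filled; rows missing both
  # covariates are honestly skipped (each target is a feature of the other)
  fillable <- sum(is.na(h$dTg_2005) & !is.na(h$dTl_2005))
  expect_equal(out$reports$dTg_2005$n_imputed, fillable)
  # dTl pass runs after dTg and can use every record whose dTg is now present
  expect_false(anyNA(out$records$dTl_2005[!is.na(out$records$dTg_2005)]))
})
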