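#' Candidate feature sets for covariate imputation
#'
#' Returns the candidate predictor sets compared by cross-validation when
#' imputing a missing climate covariate. For the local temperature rise the
#' pool holds four models: the full six-variable set (global rise,
#' area-weighted current temperature, latitude, longitude, future midpoint
#' year, emission scenario) and successive reductions down to the
#' three-variable set \{global rise, latitude, longitude\}. For the
#' precipitation change the pool includes the seven-variable set ending in
#' current annual precipitation; for the global rise, the stated
#' six-variable set and reductions.
#'
#' @param target `"dTl_2005"`, `"dTg_2005"` or `"dPr"`.
#' @return Named list of character vectors (feature sets), in the order they
#'   are compared.
#' @export
default_candidates <- function(target) {
  switch(target,
    dTl_2005 = list(
      full6 = c("dTg_2005", "Tave_w", "lat", "lon", "future_mid", "scenario"),
      no_scenario = c("dTg_2005", "Tave_w", "lat", "lon", "future_mid"),
      no_period = c("dTg_2005", "Tave_w", "lat", "lon"),
      reduced3 = c("dTg_2005", "lat", "lon")),
    dTg_2005 = list(
      full6 = c("dTl_2005", "Tave_w", "lat", "lon", "scenario", "future_mid"),
      no_scenario = c("dTl_2005", "Tave_w", "lat", "lon", "future_mid"),
      reduced = c("dTl_2005", "lat", "lon")),
    dPr = list(
      full8 = c("Pr_base", "Tave_w", "lat", "lon", "dTl_2005", "scenario",
                "future_mid", "YI_2005"),
      best7 = c("dTg_2005", "dTl_2005", "lat", "lon", "scenario",
                "future_mid", "Pr_base"),
      reduced5 = c("Pr_base", "lat", "lon", "dTl_2005", "future_mid"),
      reduced3 = c("Pr_base", "lat", "lon")),
    stop("unknown imputation target: ", target)
  )
}

# one-hot design matrix; categorical levels fixed alphabetically from the
# training data so train/predict encodings agree and are deterministic
make_encoder <- function(records, features) {
  unknown <- setdiff(features, names(records))
  if (length(unknown)) {
    stop("unknown feature name(s): ", paste(unknown, collapse = ", "))
  }
  spec <- lapply(features, function(f) {
    v <- records[[f]]
    if (is.numeric(v) || is.integer(v)) {
      list(kind = "numeric")
    } else {
      lv <- sort(unique(as.character(v[!is.na(v)])))
      if (!length(lv)) stop("feature has no observed values: ", f)
      list(kind = "categorical", levels = lv)
    }
  })
  names(spec) <- features
  structure(list(features = features, spec = spec), class = "rf_encoder")
}

encode_features <- function(encoder, records) {
  cols <- list()
  grp <- integer(0)
  for (k in seq_along(encoder$features)) {
    f <- encoder$features[k]
    sp <- encoder$spec[[f]]
    v <- records[[f]]
    if (sp$kind == "numeric") {
      cols[[f]] <- as.numeric(v)
      grp <- c(grp, k)
    } else {
      v <- as.character(v)
      for (lv in sp$levels) {
        cols[[paste(f, lv, sep = ".")]] <-
          ifelse(is.na(v), NA_real_, as.numeric(v == lv))
        grp <- c(grp, k)
      }
    }
  }
  out <- do.call(cbind, cols)
  attr(out, "col_groups") <- grp
  out
}

#' Fit a covariate imputer with cross-validated feature-set selection
#'
#' For each candidate feature set, computes a k-fold cross-validated RMSE and
#' an out-of-bag explained variance (OOB R-squared x 100) on the records
#' where the target is observed, then refits on all complete records with
#' the winning set (highest explained variance). Deterministic given `seed`.
#'
#' @param records Corpus data.frame.
#' @param target Column to impute (`"dTl_2005"`, `"dTg_2005"` or `"dPr"`).
#' @param candidates Named list of feature sets (see [default_candidates()]).
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed covering fold assignment and all forests.
#' @param num_trees Trees per forest (default 500).
#' @param mtry Predictors tried per split (see [crop_rf()]).
#' @param min_node Minimum split node size.
#' @param min_train Minimum number of complete training records.
#' @return List with `model` (the fitted imputer: forest, encoder, feature
#'   set, target) and `report` (class `imputation_report`: per-candidate
#'   `cv_rmse` and `oob_explained_variance`, the `selected` set, `n_train`,
#'   `seed`).
#' @export
fit_imputer <- function(records, target, candidates = default_candidates(target),
                        folds = 10, seed = 42, num_trees = 500, mtry = "all",
                        min_node = 5, min_train = 50) {
  if (!target %in% names(records)) stop("target not a record field: ", target)
  if (!length(candidates)) stop("no candidate feature sets")
  if (is.null(names(candidates))) {
    names(candidates) <- vapply(candidates, paste, "", collapse = "+")
  }
  all_feats <- unique(unlist(candidates))
  unknown <- setdiff(all_feats, names(records))
  if (length(unknown)) {
    stop("unknown feature name(s): ", paste(unknown, collapse = ", "))
  }

  have <- !is.na(records[[target]])
  complete <- have
  for (f in all_feats) complete <- complete & !is.na(records[[f]])
  train <- records[complete, , drop = FALSE]
  n <- nrow(train)
  if (n < min_train) {
    stop("too few complete records to train (", n, " < ", min_train, ")")
  }
  y <- as.numeric(train[[target]])
  fold_of <- with_seed(seed, sample(rep_len(seq_len(folds), n)))

  eval_one <- function(feats, cand_idx) {
    enc <- make_encoder(train, feats)
    x <- encode_features(enc, train)
    grp <- attr(x, "col_groups")
    sq_err <- numeric(0)
    for (k in seq_len(folds)) {
      hold <- fold_of == k
      if (!any(hold) || sum(!hold) < 2) next
      fit <- crop_rf(x[!hold, , drop = FALSE], y[!hold],
                     num_trees = num_trees, mtry = mtry, min_node = min_node,
                     seed = seed + 1000L * cand_idx + k, col_groups = grp)
      pred <- rf_predict_cpp(unclass(fit), x[hold, , drop = FALSE])
      sq_err <- c(sq_err, (pred - y[hold])^2)
    }
    full <- crop_rf(x, y, num_trees = num_trees, mtry = mtry,
                    min_node = min_node, seed = seed + 1000L * cand_idx,
                    col_groups = grp)
    list(cv_rmse = sqrt(mean(sq_err)),
         oob_ev = 100 * full$oob_r2,
         fit = full, encoder = enc)
  }

  evals <- Map(eval_one, candidates, seq_along(candidates))
  cand_tbl <- data.frame(
    candidate = names(candidates),
    feature_set = vapply(candidates, paste, "", collapse = "+"),
    cv_rmse = vapply(evals, `[[`, 0, "cv_rmse"),
    oob_explained_variance = vapply(evals, `[[`, 0, "oob_ev"),
    row.names = NULL, stringsAsFactors = FALSE)

  ev <- cand_tbl$oob_explained_variance
  win <- if (all(is.na(ev))) 1L else which.max(ev) # constant target: all NA
  model <- structure(list(target = target,
                          features = candidates[[win]],
                          encoder = evals[[win]]$encoder,
                          forest = evals[[win]]$fit),
                     class = "crop_imputer")
  report <- structure(list(target = target, candidates = cand_tbl,
                           selected = names(candidates)[win],
                           selected_features = candidates[[win]],
                           n_train = n, n_imputed = NA_integer_,
                           folds = folds, num_trees = num_trees, seed = seed),
                      class = "imputation_report")
  list(model = model, report = report)
}

#' @export
print.imputation_report <- function(x, ...) {
  cat("Imputation model comparison for", x$target,
      sprintf("(n = %d, %d-fold CV, %d trees)\n", x$n_train, x$folds,
              x$num_trees))
  print(x$candidates, row.names = FALSE)
  cat("selected:", x$selected, "\n")
  invisible(x)
}

#' Fill missing covariate values with a fitted imputer
#'
#' Only records with the target missing and every model feature observed are
#' filled; their `imputed_fields` column gains the target name. Records
#' already complete pass through unchanged; rows missing a model feature are
#' left unimputed and listed in the skip report.
#'
#' @param records Corpus data.frame.
#' @param model A fitted imputer from [fit_imputer()].
#' @param target Target column; must match the model's target.
#' @return List with `records` (filled corpus), `n_imputed`, and `skipped`
#'   (row indices that could not be imputed for lack of features).
#' @export
impute_missing <- function(records, model, target = model$target) {
  if (!inherits(model, "crop_imputer")) stop("model is not a crop_imputer")
  if (!identical(target, model$target)) {
    stop("model was fitted for ", model$target, ", not ", target)
  }
  todo <- is.na(records[[target]])
  usable <- todo
  for (f in model$features) usable <- usable & !is.na(records[[f]])
  skipped <- which(todo & !usable)
  if (any(usable)) {
    x <- encode_features(model$encoder, records[usable, , drop = FALSE])
    records[[target]][usable] <- rf_predict_cpp(unclass(model$forest), x)
    if ("imputed_fields" %in% names(records)) {
      prev <- records$imputed_fields[usable]
      prev[is.na(prev)] <- ""
      records$imputed_fields[usable] <-
        ifelse(nzchar(prev), paste(prev, target, sep = ","), target)
    }
  }
  list(records = records, n_imputed = sum(usable), skipped = skipped)
}

#' Impute several targets in dependency order
#'
#' Convenience wrapper running [fit_imputer()] and [impute_missing()] for a
#' sequence of targets in the order global rise, local rise, precipitation
#' change (features of later targets depend on earlier ones).
#'
#' @param records Harmonized corpus.
#' @param targets Targets in imputation order.
#' @param folds,seed,num_trees Passed to [fit_imputer()].
#' @return List with `records` and per-target `reports`.
#' @export
impute_climate_covariates <- function(records,
                                      targets = c("dTg_2005", "dTl_2005",
                                                  "dPr"),
                                      folds = 10, seed = 42, num_trees = 500) {
  reports <- list()
  for (tg in targets) {
    if (!any(is.na(records[[tg]]))) next
    fit <- fit_imputer(records, tg, folds = folds, seed = seed,
                       num_trees = num_trees)
    res <- impute_missing(records, fit$model)
    fit$report$n_imputed <- res$n_imputed
    records <- res$records
    reports[[tg]] <- fit$report
  }
  list(records = records, reports = reports)
}
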