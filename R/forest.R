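#' Random-forest regressor
#'
#' Bagged CART regression trees with variance-reduction splits and per-node
#' feature subsampling, with out-of-bag predictions for internal validation.
#' Implemented in compiled code inside the package so the pipeline has no
#' dependency on an external forest library. Deterministic given `seed`.
#'
#' @param x Numeric matrix of predictors (no missing values).
#' @param y Numeric response, `length(y) == nrow(x)`.
#' @param num_trees Number of trees (default 500).
#' @param mtry Predictors tried per split. Default: all `p` predictors
#'   (randomness from the bootstrap alone), the regression default of the
#'   reference ensemble-tree stack; `"third"` selects the
#'   `max(1, floor(p / 3))` convention of classical forests.
#' @param min_node Minimum node size for a split (default 5).
#' @param seed Integer seed for the forest's own RNG.
#' @param col_groups Integer vector (1-based) assigning each column of `x`
#'   to a predictor: the one-hot columns of a categorical share a group and
#'   count as a single draw in the mtry subsample, as a factor does in a
#'   classical forest. Default: every column its own predictor.
#' @return Object of class `crop_rf` with elements `oob_pred`, `oob_r2`
#'   (out-of-bag R-squared) and the fitted trees.
#' @export
crop_rf <- function(x, y, num_trees = 500, mtry = NULL, min_node = 5,
                    seed = 1, col_groups = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x) || anyNA(y)) stop("missing values in training data")
  if (is.null(col_groups)) col_groups <- seq_len(ncol(x))
  p <- max(col_groups)
  if (is.null(mtry) || identical(mtry, "all")) mtry <- p
  else if (identical(mtry, "third")) mtry <- max(1L, floor(p / 3))
  fit <- rf_fit_cpp(x, as.numeric(y), as.integer(num_trees),
                    as.integer(mtry), as.integer(min_node), as.integer(seed),
                    as.integer(col_groups) - 1L)
  fit$feature_names <- colnames(x)
  class(fit) <- "crop_rf"
  fit
}

#' @param object A `crop_rf` fit.
#' @param newdata Numeric matrix with the training columns.
#' @param ... Unused.
#' @rdname crop_rf
#' @export
predict.crop_rf <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (!is.null(object$feature_names)) {
    if (!all(object$feature_names %in% colnames(newdata))) {
      stop("newdata lacks training features")
    }
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  if (anyNA(newdata)) stop("missing values in prediction data")
  rf_predict_cpp(unclass(object), newdata)
}

#' @export
print.crop_rf <- function(x, ...) {
  cat("Random-forest regression:", x$num_trees, "trees, mtry", x$mtry,
      "\n  n =", x$n_train, " OOB R^2 =", round(x$oob_r2, 4), "\n")
  invisible(x)
}

# evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
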