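# Random forest and gradient boosting on the package's C++ CART tree.
# Two boosting growth policies are exposed: depth-wise (a depth cap, the
# classical XGBoost default) and leaf-wise (a leaf-count cap, the LightGBM
# default). Both are served by one best-first grower.

MAX_INT <- .Machine$integer.max

bin_matrix <- function(X, max_bins = 64L) .cpp_bin_matrix(X, max_bins)

grow_tree <- function(binned, y, rows, mtry, max_depth, max_leaves,
                      min_node) {
  .cpp_grow_tree(binned, y, as.integer(rows - 1L), as.integer(mtry),
                 as.integer(max_depth), as.integer(max_leaves),
                 as.integer(min_node))
}

#' Fit a random forest regressor
#'
#' Bagged CART trees with per-node feature subsampling.
#'
#' @param X numeric matrix (rows = observations).
#' @param y numeric response.
#' @param ntree number of trees.
#' @param mtry_frac fraction of features considered per split.
#' @param max_depth per-leaf depth cap.
#' @param min_node minimum observations per child.
#' @param seed integer seed (fit is deterministic given it).
#' @return a `yc_rf` object with `predict()` support and a split-gain
#'   `importance` vector (diagnostic only).
#' @export
rf_fit <- function(X, y, ntree = 300, mtry_frac = 1 / 3, max_depth = 20,
                   min_node = 5, seed = 0L) {
  X <- as.matrix(X)
  mtry <- max(1L, floor(mtry_frac * ncol(X)))
  binned <- bin_matrix(X)
  with_seed(seed, {
    trees <- vector("list", ntree)
    gain <- numeric(ncol(X))
    for (b in seq_len(ntree)) {
      rows <- sample.int(nrow(X), replace = TRUE)
      trees[[b]] <- grow_tree(binned, y, rows, mtry, max_depth, MAX_INT,
                              min_node)
      gain <- gain + trees[[b]]$gain
    }
    structure(list(trees = trees, features = colnames(X),
                   importance = setNames(gain / ntree, colnames(X))),
              class = "yc_rf")
  })
}

#' @export
predict.yc_rf <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$features)) X <- X[, object$features, drop = FALSE]
  as.numeric(.cpp_predict_forest(object$trees, X))
}

#' Fit a gradient-boosted tree regressor (squared loss)
#'
#' Sequential trees on residuals with shrinkage, optional row subsampling
#' and feature subsampling. `max_depth` bounds depth-wise growth;
#' `max_leaves` bounds leaf-wise growth (set the one you do not want to
#' bind to a large value).
#'
#' @inheritParams rf_fit
#' @param learn_rate shrinkage in (0, 1].
#' @param max_leaves leaf-count cap per tree.
#' @param subsample fraction of rows per tree (without replacement).
#' @return a `yc_gbm` object with `predict()` support.
#' @export
gbm_fit <- function(X, y, ntree = 300, learn_rate = 0.1, max_depth = 6,
                    max_leaves = MAX_INT, min_node = 10, subsample = 1,
                    mtry_frac = 1, seed = 0L) {
  X <- as.matrix(X)
  mtry <- max(1L, floor(mtry_frac * ncol(X)))
  binned <- bin_matrix(X)
  with_seed(seed, {
    f0 <- mean(y)
    resid <- y - f0
    trees <- vector("list", ntree)
    for (b in seq_len(ntree)) {
      rows <- if (subsample < 1)
        sample.int(nrow(X), max(2L, floor(subsample * nrow(X))))
      else seq_len(nrow(X))
      tr <- grow_tree(binned, resid, rows, mtry, max_depth, max_leaves,
                      min_node)
      trees[[b]] <- tr
      resid <- resid - learn_rate * as.numeric(.cpp_predict_tree(tr, X))
    }
    structure(list(trees = trees, f0 = f0, learn_rate = learn_rate,
                   features = colnames(X)),
              class = "yc_gbm")
  })
}

#' @export
predict.yc_gbm <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$features)) X <- X[, object$features, drop = FALSE]
  pred <- rep(object$f0, nrow(X))
  for (tr in object$trees)
    pred <- pred + object$learn_rate * as.numeric(.cpp_predict_tree(tr, X))
  pred
}
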