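# The five base learners behind one interface, the year-ahead temporal
# split, Bayesian tuning, and the out-of-fold prediction matrix consumed by
# the ensemble stage.

learner_families <- c("linear", "lasso", "rf", "gbA", "gbB")

#' Split a panel into a year-ahead train/test pair
#'
#' Train = all rows with `year < test_year`; test = `test_year` only. Rows
#' after the test year are excluded entirely.
#'
#' @param panel a feature panel with a `year` column.
#' @param test_year the held-out year.
#' @return list `train`, `test`.
#' @export
temporal_split <- function(panel, test_year) {
  if (!test_year %in% panel$year)
    stop_config("test_year ", test_year, " not present in panel")
  train <- panel[year < test_year]
  if (nrow(train) == 0)
    stop_config("empty-train error: no years precede ", test_year)
  list(train = train, test = panel[year == test_year])
}

#' Specify a base learner
#'
#' Families: `linear` (ordinary least squares, never tuned), `lasso`
#' (L1-penalized linear model), `rf` (random forest), `gbA`
#' (gradient boosting, depth-wise growth), `gbB` (gradient boosting,
#' leaf-wise growth). Default search spaces: lasso penalty log-uniform
#' `[1e-4, 10]`; forest trees 100-500, depth 3-20, feature fraction
#' 0.2-1; boosting trees 100-1000, learning rate log-uniform
#' `[0.005, 0.3]`, depth 3-10 (A) or leaves 8-64 (B), row subsample 0.5-1.
#'
#' @param family one of the five families (plus `knn1`, a 1-nearest-
#'   neighbour probe used in tests).
#' @param params fixed parameters (used when `tune = FALSE`, or as
#'   overrides of family defaults).
#' @param tune run Bayesian search (ignored for `linear`).
#' @param n_iter Bayesian search evaluations (paper-style default 40).
#' @param n_folds cross-validation folds for tuning scores (default 10).
#' @param space optional custom search space (named [param_range()] list).
#' @return a `yc_spec` object.
#' @export
learner_spec <- function(family, params = list(), tune = TRUE, n_iter = 40,
                         n_folds = 10, space = NULL) {
  family <- match.arg(family, c(learner_families, "knn1"))
  if (n_iter < 1 || n_folds < 2) stop_config("tuning budget must be > 0")
  if (is.null(space)) space <- default_space(family)
  if (tune && family %in% c("lasso", "rf", "gbA", "gbB") &&
      length(space) == 0)
    stop_config("search space invalid for family ", family)
  structure(list(family = family, params = params, tune = tune,
                 n_iter = n_iter, n_folds = n_folds, space = space),
            class = "yc_spec")
}

default_space <- function(family) {
  switch(family,
    lasso = list(lambda = param_range(1e-4, 10, log = TRUE)),
    rf = list(ntree = param_range(100, 500, integer = TRUE),
              max_depth = param_range(3, 20, integer = TRUE),
              mtry_frac = param_range(0.2, 1.0)),
    gbA = list(ntree = param_range(100, 1000, integer = TRUE),
               learn_rate = param_range(0.005, 0.3, log = TRUE),
               depth = param_range(3, 10, integer = TRUE),
               subsample = param_range(0.5, 1.0)),
    gbB = list(ntree = param_range(100, 1000, integer = TRUE),
               learn_rate = param_range(0.005, 0.3, log = TRUE),
               leaves = param_range(8, 64, integer = TRUE),
               subsample = param_range(0.5, 1.0)),
    list())
}

default_params <- function(family) {
  switch(family,
    lasso = list(lambda = 0.01),
    rf = list(ntree = 300, max_depth = 14, mtry_frac = 1 / 3),
    gbA = list(ntree = 300, learn_rate = 0.05, depth = 6, subsample = 0.8),
    gbB = list(ntree = 300, learn_rate = 0.05, leaves = 31, subsample = 0.8),
    list())
}

fit_family <- function(family, X, y, params, seed) {
  obj <- switch(family,
    linear = {
      Z <- cbind(`(Intercept)` = 1, X)
      fit <- stats::lm.fit(Z, y)
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0
      list(coef = cf)
    },
    lasso = glmnet::glmnet(X, y, alpha = 1, lambda = params$lambda),
    rf = rf_fit(X, y, ntree = params$ntree, mtry_frac = params$mtry_frac,
                max_depth = params$max_depth, seed = seed),
    gbA = gbm_fit(X, y, ntree = params$ntree, learn_rate = params$learn_rate,
                  max_depth = params$depth, subsample = params$subsample,
                  seed = seed),
    gbB = gbm_fit(X, y, ntree = params$ntree, learn_rate = params$learn_rate,
                  max_depth = 30, max_leaves = params$leaves,
                  subsample = params$subsample, seed = seed),
    knn1 = list(X = X, y = y),
    stop_config("unknown family ", family))
  structure(list(family = family, params = params, object = obj,
                 features = colnames(X)),
            class = "yc_model")
}

#' @export
predict.yc_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$features)) X <- X[, object$features, drop = FALSE]
  switch(object$family,
    linear = as.numeric(cbind(1, X) %*% object$object$coef),
    lasso = as.numeric(predict(object$object, newx = X,
                               s = object$params$lambda)),
    knn1 = {
      tr <- object$object
      apply(X, 1, function(r)
        tr$y[which.min(colSums((t(tr$X) - r)^2))])
    },
    predict(object$object, X))
}

make_folds <- function(n, k, seed) {
  if (k < 2 || k > n) stop_config("invalid fold count ", k, " for n = ", n)
  with_seed(derive_seed(seed, "folds"), sample(rep_len(seq_len(k), n)))
}

cv_mse <- function(family, X, y, params, n_folds, seed) {
  folds <- make_folds(nrow(X), n_folds, seed)
  errs <- vapply(seq_len(n_folds), function(f) {
    idx <- folds == f
    m <- fit_family(family, X[!idx, , drop = FALSE], y[!idx], params,
                    derive_seed(seed, paste0("cvfit", f)))
    mean((y[idx] - predict(m, X[idx, , drop = FALSE]))^2)
  }, numeric(1))
  mean(errs)
}

panel_matrix <- function(panel, features) {
  miss <- setdiff(features, names(panel))
  if (length(miss) > 0)
    stop_config("features absent from panel: ", paste(head(miss), collapse = ", "))
  as.matrix(panel[, features, with = FALSE])
}

#' Tune (Bayesian search + k-fold CV) and fit one base learner
#'
#' The plain linear family is fit directly; tunable families run
#' [bayes_optimize()] over their search space, scoring each configuration
#' by `n_folds`-fold cross-validated MSE on the training partition, then
#' refit on the full partition with the best configuration.
#'
#' @param spec a [learner_spec()].
#' @param train training feature panel (must contain `yield`).
#' @param features character vector (or `yc_featureset`) of predictor
#'   columns.
#' @param seed integer seed controlling folds, search and stochastic fits.
#' @return a fitted `yc_model` (tuned parameters in `$params`,
#'   cross-validation score of the winner in `$cv_mse`).
#' @export
tune_and_fit <- function(spec, train, features, seed = 0L) {
  stopifnot(inherits(spec, "yc_spec"))
  if (inherits(features, "yc_featureset")) features <- features$names
  X <- panel_matrix(train, features)
  y <- train$yield
  params <- utils::modifyList(default_params(spec$family), spec$params)
  cv <- NA_real_
  if (spec$family %in% c("lasso", "rf", "gbA", "gbB") && isTRUE(spec$tune)) {
    res <- bayes_optimize(
      function(p) cv_mse(spec$family, X, y,
                         utils::modifyList(params, p),
                         spec$n_folds, seed),
      spec$space, n_iter = spec$n_iter, seed = derive_seed(seed, spec$family))
    params <- utils::modifyList(params, res$par)
    cv <- res$value
  }
  m <- fit_family(spec$family, X, y, params,
                  derive_seed(seed, paste0("fit-", spec$family)))
  m$cv_mse <- cv
  m
}

new_prediction_matrix <- function(keys, y, preds, role) {
  pm <- data.table::data.table(geoid = keys$geoid, year = keys$year, y = y)
  for (nm in colnames(preds)) pm[, (nm) := preds[, nm]]
  pm[, role := role]
  structure(pm, class = c("yc_predmatrix", class(pm)),
            models = colnames(preds))
}

#' Model prediction columns of a prediction matrix, as a matrix
#' @param pm a `yc_predmatrix`.
#' @export
pm_predictions <- function(pm) {
  as.matrix(pm[, attr(pm, "models"), with = FALSE])
}

#' Collect the train and test prediction matrices for a set of models
#'
#' The train matrix holds, per model, either out-of-fold predictions (each
#' fold's rows predicted by a model refit with the same hyperparameters but
#' without those rows) or in-sample predictions. The test matrix holds each
#' model's predictions for the held-out partition. Out-of-fold is the mode
#' the ensemble weights are fitted on by default: it stops the weight
#' optimizer from rewarding the most overfit learner.
#'
#' @param models named list of fitted `yc_model`s (same training partition,
#'   same features).
#' @param train,test feature panels from [temporal_split()].
#' @param features predictor columns (character or `yc_featureset`).
#' @param mode `"out-of-fold"` or `"in-sample"` for the train matrix.
#' @param n_folds folds for out-of-fold refits.
#' @param seed integer seed (fold assignment, refits).
#' @return list `train`, `test` of `yc_predmatrix` objects.
#' @export
collect_predictions <- function(models, train, test, features,
                                mode = c("out-of-fold", "in-sample"),
                                n_folds = 10, seed = 0L) {
  mode <- match.arg(mode)
  if (inherits(features, "yc_featureset")) features <- features$names
  if (is.null(names(models)) || any(names(models) == ""))
    names(models) <- vapply(models, `[[`, "", "family")
  Xtr <- panel_matrix(train, features)
  Xte <- panel_matrix(test, features)
  k <- length(models)

  tr_pred <- matrix(NA_real_, nrow(Xtr), k,
                    dimnames = list(NULL, names(models)))
  if (mode == "in-sample") {
    for (j in seq_len(k)) tr_pred[, j] <- predict(models[[j]], Xtr)
  } else {
    folds <- make_folds(nrow(Xtr), n_folds, seed)
    if (min(table(folds)) < 2)
      stop_config("fold-size error: a fold has < 2 rows")
    for (f in seq_len(n_folds)) {
      idx <- folds == f
      for (j in seq_len(k)) {
        m <- models[[j]]
        refit <- fit_family(m$family, Xtr[!idx, , drop = FALSE],
                            train$yield[!idx], m$params,
                            derive_seed(seed, paste0("oof", f, m$family)))
        tr_pred[idx, j] <- predict(refit, Xtr[idx, , drop = FALSE])
      }
    }
  }
  te_pred <- vapply(models, function(m) predict(m, Xte),
                    numeric(nrow(Xte)))
  if (nrow(Xte) == 1) te_pred <- matrix(te_pred, 1,
                                        dimnames = list(NULL, names(models)))
  list(
    train = new_prediction_matrix(train, train$yield, tr_pred,
                                  if (mode == "out-of-fold")
                                    "train-out-of-fold" else
                                      "train-in-sample"),
    test = new_prediction_matrix(test, test$yield, te_pred, "test"))
}
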