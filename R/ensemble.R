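# The two stacking rules: equal weights, and the constrained
# optimized-weight ensemble on the probability simplex. The optimizer
# minimizes training root-mean-square error subject to (i) weights summing
# to one, (ii) nonnegative weights, (iii) the ensemble's training MSE not
# exceeding any base learner's. Because every simplex vertex is feasible
# and the simplex minimum cannot exceed the value at any vertex, the
# dominance constraint is always satisfiable; it is enforced anyway and
# reported in the diagnostics.

new_weights <- function(w, objective, diagnostics) {
  structure(list(weights = w, objective = objective,
                 diagnostics = diagnostics),
            class = "yc_weights")
}

#' @export
print.yc_weights <- function(x, ...) {
  cat("<yc_weights> objective =", format(x$objective, digits = 6), "\n")
  print(round(x$weights, 4))
  invisible(x)
}

#' Equal (average-ensemble) weights
#' @param k number of base models.
#' @return a `yc_weights` with each weight `1/k`.
#' @export
fit_average_weights <- function(k) {
  if (k < 1) stop_config("k must be >= 1")
  new_weights(rep(1 / k, k), NA_real_,
              list(converged = TRUE, iterations = 0L,
                   active_constraints = integer(0)))
}

ens_mse <- function(w, y, P) mean((y - as.numeric(P %*% w))^2)

#' Fit the optimized ensemble weights
#'
#' Solves `min_w sqrt(mean((y - P w)^2))` over the simplex, subject to the
#' per-base-learner dominance constraint (ensemble MSE less than or equal
#' to every base model's MSE), with SLSQP multi-started from the
#' equal-weight point and every simplex vertex. Minimizing the root or the
#' square gives the same argmin over the same feasible set (the root is
#' monotone); the root is used for conditioning. Weights driven
#' infinitesimally negative by the solver are clipped to zero and
#' renormalized.
#'
#' @param pm a training `yc_predmatrix` (out-of-fold by default upstream).
#' @param tol_dominance slack on the dominance constraint (default 1e-8).
#' @return a `yc_weights`: weights, objective (training RMSE, Mg/ha), and
#'   diagnostics (convergence, iterations, active constraints, start used).
#' @export
fit_optimized_weights <- function(pm, tol_dominance = 1e-8) {
  stopifnot(inherits(pm, "yc_predmatrix"))
  if (!all(grepl("^train", pm$role)))
    stop_config("weights must be fitted on a train prediction matrix")
  P <- pm_predictions(pm)
  y <- pm$y
  k <- ncol(P)
  if (k < 2) stop_config("k must be >= 2 for the optimized ensemble")
  n <- nrow(P)
  base_mse <- colMeans((y - P)^2)

  obj <- function(w) sqrt(ens_mse(w, y, P))
  grad <- function(w) {
    r <- as.numeric(P %*% w) - y
    f <- sqrt(mean(r^2))
    if (f < 1e-14) return(rep(0, k))
    as.numeric(crossprod(P, r)) / (n * f)
  }
  hin <- function(w) ens_mse(w, y, P) - base_mse   # <= 0 required
  hinjac <- function(w) {
    r <- as.numeric(P %*% w) - y
    g <- 2 * as.numeric(crossprod(P, r)) / n
    matrix(g, k, k, byrow = TRUE)
  }

  starts <- c(list(rep(1 / k, k)),
              lapply(seq_len(k), function(j) {
                w <- rep(0, k); w[j] <- 1; w
              }))
  best <- NULL
  for (s in seq_along(starts)) {
    sol <- tryCatch(
      nloptr::slsqp(starts[[s]], fn = obj, gr = grad,
                    lower = rep(0, k), upper = rep(1, k),
                    hin = hin, hinjac = hinjac,
                    heq = function(w) sum(w) - 1,
                    heqjac = function(w) matrix(1, 1, k),
                    deprecatedBehavior = FALSE,
                    control = list(xtol_rel = 1e-12, maxeval = 500)),
      error = function(e) NULL)
    if (is.null(sol)) next
    w <- sol$par
    feasible <- abs(sum(w) - 1) <= 1e-6 && all(w >= -1e-8) &&
      ens_mse(pmax(w, 0) / sum(pmax(w, 0)), y, P) <=
        min(base_mse) + tol_dominance
    if (feasible && (is.null(best) || sol$value < best$value))
      best <- list(value = sol$value, par = w, iter = sol$iter,
                   convergence = sol$convergence, start = s)
  }

  if (is.null(best)) {
    # always-feasible fallback: the vertex of the training-best base model
    j <- which.min(base_mse)
    warning("weight optimizer did not converge from any start; ",
            "falling back to the best base-model vertex")
    w <- rep(0, k); w[j] <- 1
    best <- list(value = sqrt(base_mse[j]), par = w, iter = 0L,
                 convergence = -1L, start = NA_integer_)
  }

  w <- best$par
  w[w < 1e-10] <- 0
  w <- w / sum(w)
  mse_w <- ens_mse(w, y, P)
  active <- which(abs(base_mse - mse_w) <= tol_dominance)
  new_weights(setNames(w, colnames(P)), sqrt(mse_w),
              list(converged = best$convergence > 0,
                   iterations = best$iter,
                   active_constraints = active,
                   zero_weights = which(w == 0),
                   start = best$start,
                   base_mse = base_mse))
}

compositions <- function(m, k) {
  if (k == 1) return(matrix(m, 1, 1))
  do.call(rbind, lapply(0:m, function(i)
    cbind(i, compositions(m - i, k - 1))))
}

#' Exhaustive simplex-grid oracle for the ensemble weights
#'
#' Enumerates every nonnegative weight vector on the `step`-lattice summing
#' to one, filters by the dominance constraint, and returns the minimizer.
#' A brute-force verification tool, limited to `k <= 4`.
#'
#' @param pm a training `yc_predmatrix`.
#' @param step lattice step; `1/step` must be an integer.
#' @param tol_dominance dominance slack (default 1e-8).
#' @return a `yc_weights`.
#' @export
grid_oracle_weights <- function(pm, step = 0.01, tol_dominance = 1e-8) {
  stopifnot(inherits(pm, "yc_predmatrix"))
  P <- pm_predictions(pm)
  y <- pm$y
  k <- ncol(P)
  if (k > 4) stop_config("oracle-scope error: grid oracle supports k <= 4")
  m <- round(1 / step)
  if (abs(m - 1 / step) > 1e-9) stop_config("step must divide 1")
  W <- compositions(m, k) / m
  base_mse <- colMeans((y - P)^2)

  n_cand <- nrow(W)
  mse <- numeric(n_cand)
  chunk <- 20000L
  for (i0 in seq(1L, n_cand, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n_cand)
    E <- P %*% t(W[i0:i1, , drop = FALSE]) - y
    mse[i0:i1] <- colMeans(E^2)
  }
  # mse <= every base MSE  <=>  mse <= the smallest base MSE
  ok <- mse <= min(base_mse) + tol_dominance
  idx <- which(ok)[which.min(mse[ok])]
  w <- W[idx, ]
  new_weights(setNames(w, colnames(P)), sqrt(mse[idx]),
              list(converged = TRUE, iterations = n_cand,
                   active_constraints =
                     which(abs(base_mse - mse[idx]) <= tol_dominance)))
}

#' Apply ensemble weights to a prediction matrix
#'
#' @param weights a `yc_weights` (length must equal the matrix's k).
#' @param pm a `yc_predmatrix`.
#' @return numeric predictions (Mg/ha), one per row.
#' @export
predict_ensemble <- function(weights, pm) {
  P <- pm_predictions(pm)
  w <- weights$weights
  if (length(w) != ncol(P))
    stop_config("shape error: ", length(w), " weights for ", ncol(P),
                " prediction columns")
  as.numeric(P %*% w)
}
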