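# Sequential model-based (Bayesian) optimization: a Gaussian-process
# surrogate with an RBF kernel on unit-scaled parameters and an
# expected-improvement acquisition, maximized over a seeded candidate set.
# Small and dependency-free; deterministic given the seed.

#' Define one tunable parameter
#' @param lower,upper bounds on the original scale.
#' @param log search on the log scale.
#' @param integer round to integer after unscaling.
#' @export
param_range <- function(lower, upper, log = FALSE, integer = FALSE) {
  stopifnot(lower < upper, !log || lower > 0)
  list(lower = lower, upper = upper, log = log, integer = integer)
}

unscale_params <- function(u, space) {
  out <- vector("list", length(space))
  names(out) <- names(space)
  for (j in seq_along(space)) {
    s <- space[[j]]
    v <- if (s$log) exp(log(s$lower) + u[j] * (log(s$upper) - log(s$lower)))
    else s$lower + u[j] * (s$upper - s$lower)
    if (s$integer) v <- as.integer(round(v))
    out[[j]] <- v
  }
  out
}

gp_posterior <- function(U, yv, Ustar, lengthscale = 0.25, nugget = 1e-6) {
  sqd <- function(A, B) {
    an <- rowSums(A^2); bn <- rowSums(B^2)
    pmax(outer(an, bn, `+`) - 2 * A %*% t(B), 0)
  }
  mu0 <- mean(yv); s0 <- sd(yv); if (!is.finite(s0) || s0 == 0) s0 <- 1
  z <- (yv - mu0) / s0
  K <- exp(-0.5 * sqd(U, U) / lengthscale^2) + diag(nugget, nrow(U))
  Ks <- exp(-0.5 * sqd(Ustar, U) / lengthscale^2)
  L <- chol(K)
  alpha <- backsolve(L, backsolve(L, z, transpose = TRUE))
  mu <- as.numeric(Ks %*% alpha)
  v <- backsolve(L, t(Ks), transpose = TRUE)
  s2 <- pmax(1 - colSums(v^2), 1e-12)
  list(mu = mu0 + s0 * mu, sd = s0 * sqrt(s2))
}

#' Minimize a black-box objective by GP-based Bayesian search
#'
#' @param fn function taking a named parameter list, returning a scalar to
#'   minimize (e.g. cross-validated MSE).
#' @param space named list of [param_range()]s.
#' @param n_iter total number of objective evaluations.
#' @param n_init size of the initial random design (rest is EI-guided).
#' @param seed integer seed.
#' @param n_candidates candidate points scored by EI per iteration.
#' @return list `par` (best parameter list), `value`, and the evaluation
#'   `history` (data.frame of unit-scaled points and objective values).
#' @export
bayes_optimize <- function(fn, space, n_iter = 40, n_init = 8, seed = 0L,
                           n_candidates = 256) {
  stopifnot(n_iter >= 1, length(space) >= 1)
  d <- length(space)
  n_init <- min(n_init, n_iter)
  with_seed(derive_seed(seed, "bayesopt"), {
    U <- matrix(runif(n_init * d), n_init, d)
    U[1, ] <- 0.5  # always probe the centre of the space
    yv <- apply(U, 1, function(u) fn(unscale_params(u, space)))
    while (length(yv) < n_iter) {
      cand <- matrix(runif(n_candidates * d), n_candidates, d)
      post <- gp_posterior(U, yv, cand)
      best <- min(yv)
      zq <- (best - post$mu) / post$sd
      ei <- (best - post$mu) * pnorm(zq) + post$sd * stats::dnorm(zq)
      # avoid re-evaluating a point we already have
      dup <- apply(cand, 1, function(u)
        min(colSums((t(U) - u)^2)) < 1e-10)
      ei[dup] <- -Inf
      u_next <- cand[which.max(ei), , drop = FALSE]
      U <- rbind(U, u_next)
      yv <- c(yv, fn(unscale_params(u_next[1, ], space)))
    }
    i <- which.min(yv)
    list(par = unscale_params(U[i, ], space), value = yv[i],
         history = data.frame(U, value = yv))
  })
}
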