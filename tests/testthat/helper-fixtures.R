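# Shared fixtures: all built in code, no stored data.

# the default stated-world panel: 12 states x 2 CRDs x 3 counties, 1984-2020
default_panels <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_scenario(scenario_config(seed = 0))
    cache
  }
})

# a small fast panel for pipeline-level tests
tiny_scenario <- function(seed = 0, ...) {
  scenario_config(n_states = 4, crds_per_state = 1, counties_per_crd = 3,
                  years = 1996:2020, shock = list(n_counties = 3),
                  seed = seed, ...)
}

# random prediction matrix: k models = truth + per-model bias + noise
random_pm <- function(n = 200, k = 3, seed = 0, role = "train-out-of-fold") {
  set.seed(seed)
  y <- rnorm(n, 10, 1.5)
  P <- sapply(seq_len(k), function(j)
    y + rnorm(1, 0, 0.3) + rnorm(n, 0, 0.3 + 0.2 * j))
  colnames(P) <- paste0("m", seq_len(k))
  keys <- data.frame(geoid = sprintf("%05d", seq_len(n)), year = 2000L)
  yieldcast:::new_prediction_matrix(keys, y, P, role)
}

# hand-built prediction matrix from explicit columns
pm_from_cols <- function(y, ..., role = "train-out-of-fold") {
  P <- cbind(...)
  colnames(P) <- paste0("m", seq_len(ncol(P)))
  keys <- data.frame(geoid = sprintf("%05d", seq_along(y)), year = 2000L)
  yieldcast:::new_prediction_matrix(keys, y, P, role)
}

# small regression panel with a year column, for selection/learner tests:
# linear signal on the first n_signal features, the rest pure noise
signal_panel <- function(n_counties = 50, years = 2001:2011, n_signal = 5,
                         n_noise = 50, snr = 10, seed = 0) {
  set.seed(seed)
  n <- n_counties * length(years)
  p <- n_signal + n_noise
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- sprintf("f%02d", seq_len(p))
  beta <- rep(1, n_signal)
  signal <- X[, seq_len(n_signal), drop = FALSE] %*% beta
  noise_sd <- sqrt(as.numeric(var(signal)) / snr)
  y <- as.numeric(signal) + rnorm(n, 0, noise_sd)
  dt <- data.table::data.table(
    geoid = rep(sprintf("%05d", seq_len(n_counties)), length(years)),
    year = rep(years, each = n_counties), yield = y)
  cbind(dt, data.table::as.data.table(X))
}
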