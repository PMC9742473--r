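# The experiment runner: per test year, split -> preprocess (trend fit on
# training years only) -> expert filter -> permutation selection -> five
# tuned base learners -> both ensembles -> evaluation -> error analysis.

#' Configure an end-to-end run
#'
#' @param scenario a [scenario_config()] or a directory path holding the
#'   six scenario CSVs.
#' @param test_years held-out years, each predicted with models trained on
#'   all preceding years (rolling origin; hyperparameters re-tuned per
#'   year).
#' @param k number of features kept by permutation selection.
#' @param ensemble_mode `"out-of-fold"` or `"in-sample"` train predictions
#'   for the weight fit.
#' @param include_apsim include the 37 crop-model columns.
#' @param learners base-learner families to fit (default all five).
#' @param learner_params named list of per-family parameter overrides
#'   (e.g. `list(rf = list(ntree = 80))`), applied on top of family
#'   defaults — the knob used to scale runs down for constrained budgets.
#' @param tune Bayesian-tune the learners (FALSE pins family defaults).
#' @param n_iter,cv_folds Bayesian-search budget per learner.
#' @param oof_folds folds for out-of-fold stacking predictions.
#' @param selection `forest_config` list for
#'   [rank_features_permutation()].
#' @param seed root seed; every stage derives its own stream from it.
#' @param outdir optional directory for CSV/JSON artifacts.
#' @return a `yc_runconfig` list.
#' @export
run_config <- function(scenario = scenario_config(),
                       test_years = c(2018, 2019, 2020), k = 100,
                       ensemble_mode = c("out-of-fold", "in-sample"),
                       include_apsim = TRUE,
                       learners = learner_families,
                       learner_params = list(), tune = TRUE,
                       n_iter = 40, cv_folds = 10, oof_folds = 10,
                       selection = list(), seed = 0L, outdir = NULL) {
  ensemble_mode <- match.arg(ensemble_mode)
  if (k <= 0) stop_config("k must be > 0")
  if (length(test_years) == 0) stop_config("no test years")
  structure(list(scenario = scenario, test_years = as.integer(test_years),
                 k = k, ensemble_mode = ensemble_mode,
                 include_apsim = include_apsim, learners = learners,
                 learner_params = learner_params,
                 tune = tune, n_iter = n_iter, cv_folds = cv_folds,
                 oof_folds = oof_folds, selection = selection,
                 seed = as.integer(seed), outdir = outdir),
            class = "yc_runconfig")
}

load_panels <- function(config) {
  if (is.character(config$scenario)) read_scenario_csvs(config$scenario)
  else simulate_scenario(config$scenario)
}

#' Run the full prediction experiment
#'
#' For each test year: year-ahead split, preprocessing with the yield
#' trend fit on training years only, two-stage feature selection, the
#' configured base learners with Bayesian tuning, both ensembles, and
#' evaluation with the storm-shock exclusion applied to the test set only.
#' Afterwards, county/CRD/state error aggregation and the county-error vs
#' soil-weather correlation analysis are computed from the optimized
#' ensemble's test predictions. Deterministic given the config.
#'
#' @param config a [run_config()].
#' @return a run manifest: `config`, `per_year` (selected features,
#'   weights, metrics, prediction matrices per test year), pooled
#'   `metrics`, `region_errors`, `correlations`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "yc_runconfig"))
  panels <- load_panels(config)
  yrs <- sort(unique(panels$yield$year))
  if (!all(config$test_years %in% yrs))
    stop_config("test years outside the panel's range")

  per_year <- list()
  all_test <- list()
  metrics_rows <- list()

  for (ty in config$test_years) {
    tag <- paste0("year", ty)
    message("[", tag, "] preprocessing")
    pre <- preprocess_panels(panels, train_years = yrs[yrs < ty])
    panel <- pre$panel
    if (!config$include_apsim) {
      drop <- intersect(apsim_cols(), names(panel))
      panel <- panel[, setdiff(names(panel), drop), with = FALSE]
    }
    split <- temporal_split(panel, ty)

    message("[", tag, "] feature selection")
    fs <- expert_filter(split$train)
    ranking <- rank_features_permutation(
      split$train, fs, config$selection,
      seed = derive_seed(config$seed, paste0("select", ty)))
    sel <- select_top_k(ranking, min(config$k, nrow(ranking)))

    message("[", tag, "] fitting ", length(config$learners), " learners")
    models <- lapply(config$learners, function(fam)
      tune_and_fit(
        learner_spec(fam, params = config$learner_params[[fam]] %||% list(),
                     tune = config$tune, n_iter = config$n_iter,
                     n_folds = config$cv_folds),
        split$train, sel,
        seed = derive_seed(config$seed, paste0(fam, ty))))
    names(models) <- config$learners

    cp <- collect_predictions(models, split$train, split$test, sel,
                              mode = config$ensemble_mode,
                              n_folds = config$oof_folds,
                              seed = derive_seed(config$seed,
                                                 paste0("oof", ty)))

    message("[", tag, "] fitting ensembles")
    w_avg <- fit_average_weights(length(models))
    w_opt <- fit_optimized_weights(cp$train)

    test_pred <- data.table::copy(cp$test)
    test_pred[, ens_avg := predict_ensemble(w_avg, cp$test)]
    test_pred[, ens_opt := predict_ensemble(w_opt, cp$test)]

    kept <- apply_exclusions(test_pred, panels$yield)
    model_cols <- c(attr(cp$test, "models"), "ens_avg", "ens_opt")
    for (mc in model_cols)
      metrics_rows[[paste(ty, mc)]] <- cbind(
        data.table::data.table(year = ty, model = mc),
        compute_metrics(kept$y, kept[[mc]]))

    all_test[[tag]] <- kept[, .(geoid, year, y, yhat = ens_opt)]
    per_year[[tag]] <- list(test_year = ty, features = sel,
                            ranking = ranking, weights_opt = w_opt,
                            weights_avg = w_avg, predictions = test_pred,
                            predictions_kept = kept, trend = pre$trend,
                            excluded = attr(kept, "excluded"))
  }

  metrics <- data.table::rbindlist(metrics_rows)
  pooled <- data.table::rbindlist(all_test)
  region_errors <- list(
    county = error_by_region(pooled, panels$geography, "county"),
    crd = error_by_region(pooled, panels$geography, "crd"),
    state = error_by_region(pooled, panels$geography, "state"))

  # covariates from the last preprocessed panel (soil and climatology are
  # effectively static per county)
  pre_all <- preprocess_panels(panels,
                               train_years = yrs[yrs < max(config$test_years)])
  covs <- build_error_covariates(pre_all$panel)
  correlations <- correlate_error_features(region_errors$county, covs,
                                           panels$geography)

  manifest <- list(config = config, per_year = per_year, metrics = metrics,
                   region_errors = region_errors,
                   correlations = correlations)
  if (!is.null(config$outdir)) write_run_artifacts(manifest, config$outdir)
  manifest
}

write_run_artifacts <- function(manifest, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(manifest$metrics, file.path(outdir, "metrics.csv"))
  for (lvl in names(manifest$region_errors))
    data.table::fwrite(manifest$region_errors[[lvl]],
                       file.path(outdir, paste0("region_errors_", lvl, ".csv")))
  data.table::fwrite(manifest$correlations,
                     file.path(outdir, "correlations.csv"))
  weights <- lapply(manifest$per_year, function(py) list(
    models = names(py$weights_opt$weights),
    optimized = unname(py$weights_opt$weights),
    objective = py$weights_opt$objective,
    average = unname(py$weights_avg$weights),
    diagnostics = py$weights_opt$diagnostics[c("converged", "iterations")]))
  jsonlite::write_json(weights, file.path(outdir, "weights.json"),
                       auto_unbox = TRUE, digits = NA)
  for (tag in names(manifest$per_year)) {
    py <- manifest$per_year[[tag]]
    data.table::fwrite(py$predictions,
                       file.path(outdir, paste0("predictions_", py$test_year,
                                                ".csv")))
    data.table::fwrite(py$ranking,
                       file.path(outdir, paste0("ranking_", py$test_year,
                                                ".csv")))
    jsonlite::write_json(py$features$names,
                         file.path(outdir, paste0("selected_features_",
                                                  py$test_year, ".json")))
  }
  invisible(outdir)
}

#' Paired with/without-crop-model comparison
#'
#' Runs the experiment twice per seed on identical synthetic data — once
#' with the 37 crop-model columns available to selection and once without —
#' and reports the paired test RMSE of the optimized ensemble.
#'
#' @param config a [run_config()] (its `include_apsim` flag is overridden).
#' @param n_seeds number of paired replicate scenarios (>= 2).
#' @return data.table with one row per (seed, arm); attributes
#'   `mean_difference` (without minus with; positive favours the
#'   crop-model features) and `wins_with_apsim` (seeds where the
#'   crop-model arm has strictly lower RMSE).
#' @export
compare_with_without_apsim <- function(config, n_seeds = 10) {
  stopifnot(inherits(config, "yc_runconfig"))
  if (n_seeds < 2) stop_config("n_seeds must be >= 2")
  if (is.character(config$scenario))
    stop_config("the paired comparison needs a generative scenario config")
  rows <- list()
  for (s in seq_len(n_seeds)) {
    sc <- config$scenario
    sc$seed <- derive_seed(config$seed, paste0("pair", s))
    for (arm in c(TRUE, FALSE)) {
      cfg <- config
      cfg$scenario <- sc
      cfg$include_apsim <- arm
      cfg$seed <- sc$seed
      cfg$outdir <- NULL
      res <- run_experiment(cfg)
      pooled <- data.table::rbindlist(
        lapply(res$per_year, function(py)
          py$predictions_kept[, .(y, ens_opt)]))
      rows[[paste(s, arm)]] <- data.table::data.table(
        seed = s, with_apsim = arm,
        rmse = sqrt(mean((pooled$y - pooled$ens_opt)^2)))
    }
  }
  out <- data.table::rbindlist(rows)
  wide <- data.table::dcast(out, seed ~ with_apsim, value.var = "rmse")
  data.table::setnames(wide, c("seed", "without", "with"))
  data.table::setattr(out, "mean_difference", mean(wide$without - wide$with))
  data.table::setattr(out, "wins_with_apsim", sum(wide$with < wide$without))
  out[]
}
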