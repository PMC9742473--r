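# Evaluation: RMSE / relative RMSE / mean bias error / R-squared, the
# storm-shock exclusion rule, regional aggregation with cropland ratio,
# and the county-error vs soil-weather correlation analysis.

metric_core <- function(y, yhat) {
  n <- length(y)
  rmse <- sqrt(mean((y - yhat)^2))
  mbe <- mean(yhat - y)
  rrmse <- if (mean(y) == 0) {
    warning("zero-mean truth in a scope: relative RMSE undefined")
    NA_real_
  } else 100 * rmse / mean(y)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) {
    warning("zero-variance truth in a scope: R-squared undefined")
    NA_real_
  } else 1 - sum((y - yhat)^2) / tss
  list(n_obs = n, rmse = rmse, rrmse = rrmse, mbe = mbe, r2 = r2)
}

#' Compute RMSE, relative RMSE, mean bias error and R-squared
#'
#' RMSE is the root of the mean squared prediction error; relative RMSE is
#' RMSE divided by the mean of the observed values, in percent; mean bias
#' error is the signed mean of predicted minus observed; R-squared is
#' `1 - RSS/TSS` (and may be negative on held-out data — it is not
#' clamped).
#'
#' @param truth,predictions aligned numeric vectors (Mg/ha).
#' @param scope optional data.frame/list of grouping columns (same length);
#'   omitted = one overall row.
#' @return data.table with the scope columns plus `n_obs`, `rmse`,
#'   `rrmse` (%), `mbe`, `r2`.
#' @export
compute_metrics <- function(truth, predictions, scope = NULL) {
  stopifnot(length(truth) == length(predictions), length(truth) > 0)
  dt <- data.table::data.table(y = truth, yhat = predictions)
  if (is.null(scope)) {
    out <- dt[, metric_core(y, yhat)]
  } else {
    scope <- data.table::as.data.table(scope)
    stopifnot(nrow(scope) == nrow(dt))
    dt <- cbind(scope, dt)
    out <- dt[, metric_core(y, yhat), by = names(scope)]
  }
  out[]
}

#' Remove shock-flagged county-years from an evaluation set
#'
#' Evaluation-only: training artifacts are never touched. Rows of the test
#' panel whose (geoid, year) appears among the flags are dropped.
#'
#' @param test_panel any table with `geoid` and `year`.
#' @param shock_flags a table with `geoid`, `year` and (optionally) a
#'   logical `shock_flag` column restricting which rows count as flagged.
#' @return the filtered panel; `attr(, "excluded")` holds the removal count.
#' @export
apply_exclusions <- function(test_panel, shock_flags) {
  test_panel <- data.table::as.data.table(test_panel)
  flags <- data.table::as.data.table(shock_flags)
  if ("shock_flag" %in% names(flags)) flags <- flags[shock_flag == TRUE]
  if (nrow(flags) == 0) {
    data.table::setattr(test_panel, "excluded", 0L)
    return(test_panel[])
  }
  keep <- !(paste(test_panel$geoid, test_panel$year) %in%
              paste(flags$geoid, flags$year))
  out <- test_panel[keep]
  data.table::setattr(out, "excluded", sum(!keep))
  message(sum(!keep), " shock-flagged county-years excluded from evaluation")
  out[]
}

#' Aggregate prediction errors by county, CRD or state
#'
#' Metrics are computed within each region over its county-year
#' observations and joined with the region's mean cropland ratio, the
#' covariate the reliability analysis relates errors to.
#'
#' @param predictions table with `geoid`, `year`, `y`, `yhat`.
#' @param geography the geography table.
#' @param level `"county"`, `"crd"` or `"state"`.
#' @return data.table: `region`, metrics, `cropland_ratio`.
#' @export
error_by_region <- function(predictions, geography,
                            level = c("county", "crd", "state")) {
  level <- match.arg(level)
  pred <- data.table::as.data.table(predictions)
  geo <- data.table::as.data.table(geography)
  if (!all(pred$geoid %in% geo$geoid))
    stop_config("join error: unmapped geoid in predictions")
  key <- switch(level, county = "geoid", crd = "crd", state = "state")
  pred <- merge(pred, geo[, .(geoid, crd, state, cropland_ratio)],
                by = "geoid", sort = FALSE)
  out <- pred[, c(metric_core(y, yhat),
                  list(cropland_ratio = mean(cropland_ratio))),
              by = setNames(list(get(key)), "region")]
  data.table::setorder(out, region)
  out[]
}

#' Per-county soil / weather covariate summaries for the error analysis
#'
#' Averages over the panel's years: annual and summer (weeks 27-39)
#' precipitation totals and temperature means, topsoil clay, sand, organic
#' matter, pH and plant-available water, and mean water-table depth from
#' the crop-model block.
#'
#' @param panel a preprocessed feature panel.
#' @return data.table keyed by `geoid`, one covariate per column.
#' @export
build_error_covariates <- function(panel) {
  smr <- function(v, wks, agg) {
    m <- as.matrix(panel[, sprintf("wx_%s_wk%02d", v, wks), with = FALSE])
    agg(m)
  }
  dt <- data.table::data.table(
    geoid = panel$geoid,
    prcp_annual = panel$aux_prcp_tot,
    prcp_summer = smr("prcp", 27:39, rowSums),
    tmin_annual = panel$aux_tmin_mean,
    tmin_summer = smr("tmin", 27:39, rowMeans),
    tmax_annual = panel$aux_tmax_mean,
    tmax_summer = smr("tmax", 27:39, rowMeans),
    clay = panel$soil_clay_d01, sand = panel$soil_sand_d01,
    om = panel$soil_om_d01, ph = panel$soil_ph_d01,
    paw = panel$soil_paw_d01,
    water_table = panel$AnnualAvgWT)
  dt[, lapply(.SD, mean), by = geoid]
}

#' Correlate county-level RMSE with soil / weather covariates
#'
#' Pearson correlation between county RMSE and each covariate, per state
#' (states with at least `min_counties` counties) and pooled over all
#' counties, with two-sided p-values from the t transform. Constant
#' covariates yield `NA` correlations.
#'
#' @param county_metrics table with `geoid` and `rmse` (e.g. from
#'   [error_by_region()] at county level, with `region` renamed or a
#'   `geoid` column).
#' @param covariates from [build_error_covariates()].
#' @param geography optional geography enabling per-state rows.
#' @param min_counties minimum counties for a state-level correlation.
#' @return data.table: `state` ("all" for pooled), `covariate`, `r`,
#'   `p_value`, `n`.
#' @export
correlate_error_features <- function(county_metrics, covariates,
                                     geography = NULL, min_counties = 3) {
  cm <- data.table::as.data.table(county_metrics)
  if (!"geoid" %in% names(cm) && "region" %in% names(cm))
    data.table::setnames(cm, "region", "geoid")
  d <- merge(cm[, .(geoid, rmse)], covariates, by = "geoid")
  cov_names <- setdiff(names(covariates), "geoid")

  one <- function(sub, label) {
    data.table::rbindlist(lapply(cov_names, function(cv) {
      x <- sub[[cv]]; r <- sub$rmse
      if (length(x) < 3 || sd(x) == 0 || sd(r) == 0)
        return(data.table::data.table(state = label, covariate = cv,
                                      r = NA_real_, p_value = NA_real_,
                                      n = length(x)))
      ct <- stats::cor.test(r, x, method = "pearson")
      data.table::data.table(state = label, covariate = cv,
                             r = unname(ct$estimate),
                             p_value = ct$p.value, n = length(x))
    }))
  }

  out <- one(d, "all")
  if (!is.null(geography)) {
    geo <- data.table::as.data.table(geography)
    d2 <- merge(d, geo[, .(geoid, state)], by = "geoid")
    for (st in sort(unique(d2$state))) {
      sub <- d2[state == st]
      if (nrow(sub) >= min_counties) out <- rbind(out, one(sub, st))
    }
  }
  out[]
}
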