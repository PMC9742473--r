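#' Simulate weekly weather, layered soil and planting-progress panels
#'
#' Weather is generated from a state-level seasonal climatology (peak warmth
#' near week 29) plus shared state-year anomalies — so counties of a state
#' experience correlated seasons, as real panels do — plus county-week noise.
#' Growing degree days are derived from the simulated temperatures
#' (base 10 degC, weekly accumulation), so the weather block is internally
#' consistent. Soil profiles are static per county with depth-decaying
#' organic matter, texture fractions constrained to `sand + clay <= 100`,
#' and water retention ordered `wilting point <= field capacity <=
#' saturation`; plant-available water capacity is their difference. Planting
#' progress is a logistic cumulative curve per state-year, in percent.
#'
#' @param geography output of [build_geography()].
#' @param years integer year vector.
#' @param config a [scenario_config()].
#' @return list with `weather` (geoid, year + 293 columns), `soil`
#'   (geoid + 100 columns), `planting` (state, year + 52 columns).
#' @export
simulate_environment <- function(geography, years, config) {
  stopifnot(inherits(config, "yc_scenario"))
  if (nrow(geography) == 0) stop_config("empty geography")
  years <- as.integer(years)
  if (length(years) == 0) stop_config("empty year range")

  with_seed(derive_seed(config$seed, "environment"), {
    ns <- config$n_states
    st_i <- match(geography$state, config$state_codes)
    wk <- 1:52

    # state climatology: a north-south style gradient over state index
    grad <- if (ns > 1) (st_i - 1) / (ns - 1) * 2 - 1 else rep(0, nrow(geography))
    tmean_c <- 10 - 3 * grad + rnorm(nrow(geography), 0, 0.6)  # county base

    panel <- data.table::CJ(geoid = geography$geoid, year = years,
                            sorted = TRUE)
    panel[, state := geography$state[match(geoid, geography$geoid)]]
    n <- nrow(panel)
    row_cty <- match(panel$geoid, geography$geoid)
    row_sy <- match(paste(panel$state, panel$year),
                    paste(rep(config$state_codes, each = length(years)),
                          rep(years, ns)))

    # shared state-year anomalies (temperature additive, wetness multiplicative)
    t_anom <- rnorm(ns * length(years), 0, 1.2)
    wetness <- exp(rnorm(ns * length(years), 0, 0.3))
    wet_cty <- exp(rnorm(nrow(geography), 0, 0.15))

    seas_t <- 14 * cos(2 * pi * (wk - 29) / 52)
    seas_r <- 16 + 10 * cos(2 * pi * (wk - 26) / 52)
    seas_p <- 12 + 9 * cos(2 * pi * (wk - 27) / 52)

    tavg <- outer(tmean_c[row_cty] + t_anom[row_sy], rep(1, 52)) +
      outer(rep(1, n), seas_t)
    tmin <- tavg - 5 + matrix(rnorm(n * 52, 0, 1.5), n)
    tmax <- tmin + pmax(10 + matrix(rnorm(n * 52, 0, 1.5), n), 0.5)
    rad <- pmax(outer(rep(1, n), seas_r) + matrix(rnorm(n * 52, 0, 1.5), n),
                0.1)
    prcp <- outer(wetness[row_sy] * wet_cty[row_cty], seas_p) *
      matrix(rgamma(n * 52, shape = 3, rate = 3), n)
    gdd <- pmax((tmin + tmax) / 2 - 10, 0) * 7

    blocks <- list(rad = rad, prcp = prcp, tmin = tmin, tmax = tmax, gdd = gdd)
    for (v in wx_vars)
      colnames(blocks[[v]]) <- sprintf("wx_%s_wk%02d", v, wk)

    # 33 auxiliary seasonal summaries
    mo <- month_of_week()
    qtr <- rep(1:4, each = 13)
    aux <- cbind(
      vapply(1:12, function(m)
        rowMeans((tmin + tmax)[, mo == m, drop = FALSE] / 2), numeric(n)),
      vapply(1:12, function(m)
        rowSums(prcp[, mo == m, drop = FALSE]), numeric(n)),
      vapply(1:4, function(q)
        rowSums(rad[, qtr == q, drop = FALSE]), numeric(n)),
      rowSums(rad), rowSums(prcp), rowSums(gdd), rowMeans(tmin),
      rowMeans(tmax))
    colnames(aux) <- aux_weather_cols()

    weather <- cbind(
      data.table::data.table(geoid = panel$geoid, year = panel$year),
      data.table::as.data.table(do.call(cbind, unname(blocks))),
      data.table::as.data.table(aux))

    soil <- simulate_soil(geography)
    planting <- simulate_planting(config$state_codes, years)
    list(weather = weather[], soil = soil, planting = planting)
  })
}

# static per-county soil profiles: 10 properties x 10 depth layers
simulate_soil <- function(geography) {
  nc <- nrow(geography)
  soil <- data.table::data.table(geoid = geography$geoid)
  om_top <- exp(rnorm(nc, log(3), 0.35))           # topsoil organic matter %
  sand0 <- pmin(pmax(rnorm(nc, 35, 14), 3), 88)
  clay0 <- pmin((100 - sand0) * rbeta(nc, 3, 4), 60)
  ph0 <- rnorm(nc, 6.5, 0.45)
  for (d in 1:10) {
    om <- pmax(0.05, om_top * exp(-0.25 * (d - 1)) * exp(rnorm(nc, 0, 0.1)))
    sand <- pmin(pmax(sand0 + rnorm(nc, 0, 2), 1), 95)
    clay <- pmax(pmin(clay0 + rnorm(nc, 0, 2), 98 - sand), 1)
    ph <- pmin(pmax(ph0 + 0.03 * d + rnorm(nc, 0, 0.08), 4.5), 8.5)
    bd <- pmin(pmax(rnorm(nc, 1.3 + 0.02 * d, 0.06), 1.0), 1.8)
    sat <- pmin(pmax(0.32 + 0.0015 * clay + rnorm(nc, 0, 0.015), 0.25), 0.60)
    fc <- pmax(sat - (0.06 + 0.10 * runif(nc)), 0.10)
    wp <- pmax(fc - (0.06 + 0.10 * runif(nc)), 0.02)
    ksat <- exp(rnorm(nc, 2.0 + 0.02 * sand, 0.30))
    paw <- fc - wp                                  # the tenth property
    vals <- list(om = om, sand = sand, clay = clay, ph = ph, bd = bd,
                 wp = wp, fc = fc, sat = sat, ksat = ksat, paw = paw)
    for (p in soil_props)
      soil[, (sprintf("soil_%s_d%02d", p, d)) := vals[[p]]]
  }
  data.table::setcolorder(soil, c("geoid", soil_cols()))
  soil[]
}

# logistic cumulative planting curve per state-year, percent of crop planted
simulate_planting <- function(states, years) {
  pl <- data.table::CJ(state = states, year = as.integer(years), sorted = TRUE)
  n <- nrow(pl)
  mid <- rnorm(n, 18.5, 1.2)
  scl <- 1 + abs(rnorm(n, 1.2, 0.4))
  cum <- 100 * stats::plogis(outer(-mid, 1:52, `+`) / scl)
  colnames(cum) <- planting_cols()
  cbind(pl, data.table::as.data.table(cum))
}

#' Simulate crop-model outputs and observed county yields
#'
#' True yield is `b0_c + b1_c * year` (county-level trend) plus linear
#' effects of standardized summer precipitation, summer maximum temperature,
#' season growing degree days, topsoil organic matter and plant-available
#' water, plus Gaussian noise, minus a storm-shock reduction in flagged
#' counties at the shock year. Counties whose cropland ratio falls below the
#' configured threshold receive inflated noise when `low_cropland$factor > 1`.
#' The crop-model block's `AnnualYield` (kg/ha) is constructed to correlate
#' with true pre-shock yield at `config$apsim_fidelity`; the other 36 output
#' variables are populated within their physical ranges, loosely tied to the
#' same weather anomalies.
#'
#' @param weather,soil,planting panels from [simulate_environment()].
#' @param geography from [build_geography()].
#' @param config a [scenario_config()].
#' @return list with `apsim` (geoid, year + 37 columns) and `yield`
#'   (geoid, year, yield in Mg/ha, shock_flag).
#' @export
simulate_crop <- function(weather, soil, planting, geography, config) {
  stopifnot(inherits(config, "yc_scenario"))
  if (!all(weather$geoid %in% geography$geoid))
    stop_config("join error: weather contains geoids absent from geography")
  if (!all(geography$geoid %in% soil$geoid))
    stop_config("join error: soil is missing counties")

  with_seed(derive_seed(config$seed, "crop"), {
    key <- weather[, .(geoid, year)]
    n <- nrow(key)
    cty <- match(key$geoid, geography$geoid)
    st_i <- match(geography$state[cty], config$state_codes)

    zs <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else rep(0, length(x))
    wsum <- function(v, wks)
      rowSums(as.matrix(weather[, sprintf("wx_%s_wk%02d", v, wks), with = FALSE]))
    wmean <- function(v, wks)
      rowMeans(as.matrix(weather[, sprintf("wx_%s_wk%02d", v, wks), with = FALSE]))

    z_prcp <- zs(wsum("prcp", 27:39))
    z_tmax <- zs(wmean("tmax", 27:39))
    z_gdd <- zs(wsum("gdd", 16:43))
    z_om <- zs(soil$soil_om_d01)[match(key$geoid, soil$geoid)]
    z_paw <- zs(soil$soil_paw_d01)[match(key$geoid, soil$geoid)]

    tr <- config$trend
    nc <- nrow(geography)
    b1 <- rnorm(nc, tr$b1_mean, tr$b1_sd)
    base <- rnorm(nc, tr$base_mean, tr$base_sd) +
      rnorm(config$n_states, 0, 0.4)[match(geography$state,
                                           config$state_codes)]
    b0 <- base - b1 * tr$ref_year

    we <- config$weather_effects; se <- config$soil_effects
    signal <- b0[cty] + b1[cty] * key$year +
      we[["prcp_summer"]] * z_prcp + we[["tmax_summer"]] * z_tmax +
      we[["gdd_season"]] * z_gdd +
      se[["om_top"]] * z_om + se[["paw_top"]] * z_paw

    lowc <- geography$cropland_ratio < config$low_cropland$threshold
    sd_row <- config$noise_sd *
      ifelse(lowc[cty], config$low_cropland$factor, 1)
    y_pre <- signal + rnorm(n, 0, 1) * sd_row

    # windstorm-style shock
    shock_flag <- rep(FALSE, n)
    sh <- config$shock
    if (sh$n_counties > 0 && sh$year %in% key$year) {
      pool <- if (is.null(sh$state)) geography$geoid else
        geography$geoid[geography$state == sh$state]
      if (sh$n_counties > length(pool))
        stop_config("shock n_counties exceeds available counties")
      hit <- sample(pool, sh$n_counties)
      shock_flag <- key$geoid %in% hit & key$year == sh$year
    }
    yield <- pmax(0, y_pre - ifelse(shock_flag, sh$magnitude, 0))

    yield_panel <- data.table::data.table(
      geoid = key$geoid, year = key$year, yield = yield,
      shock_flag = shock_flag)

    apsim <- simulate_apsim(key, y_pre, z_prcp, z_tmax, config$apsim_fidelity)
    list(apsim = apsim, yield = yield_panel[])
  })
}

# the 37 crop-model output columns (Table-style schema), all within their
# physical ranges; AnnualYield carries the configured fidelity to true yield
simulate_apsim <- function(key, y_pre, z_prcp, z_tmax, fidelity) {
  n <- nrow(key)
  mu <- mean(y_pre); s <- sd(y_pre)
  if (!is.finite(s) || s == 0) s <- 0
  ay_mg <- if (fidelity >= 1 || s == 0) y_pre else
    mu + s * (fidelity * (y_pre - mu) / s +
                sqrt(1 - fidelity^2) * rnorm(n))
  ap <- data.table::data.table(geoid = key$geoid, year = key$year)
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  ap[, AnnualYield := pmax(0, ay_mg) * 1000]
  ap[, AnnualBiomass := AnnualYield / 0.5 * exp(rnorm(n, 0, 0.05))]
  ap[, AnnualRootD := pmax(200, rnorm(n, 1500, 200))]
  ap[, DOY_Flowering := pmin(366, pmax(1, round(rnorm(n, 195, 5))))]
  ap[, DOY_Maturity := pmin(366, pmax(1, round(rnorm(n, 260, 7))))]
  ap[, AnnualLaiMax := pmax(0.5, rnorm(n, 5, 0.7))]
  ap[, AnnualET := pmax(100, rnorm(n, 550, 60) + 20 * z_prcp)]
  ap[, MaizeTranspiration := 0.55 * AnnualET * exp(rnorm(n, 0, 0.05))]
  ap[, AnnualNupt := pmax(50, rnorm(n, 220, 30))]
  ap[, AnnualGrainlNupt := 0.6 * AnnualNupt * exp(rnorm(n, 0, 0.05))]
  ap[, AvgDroughtStress := clamp01(stats::plogis(-1.5 - 0.8 * z_prcp +
                                                   rnorm(n, 0, 0.3)))]
  ap[, AvgExcessWStress := clamp01(stats::plogis(-2 + 0.7 * z_prcp +
                                                   rnorm(n, 0, 0.3)))]
  ap[, AvgNStress := clamp01(rbeta(n, 2, 10))]
  ap[, AnnualAvgWT := pmax(100, rnorm(n, 1800, 400))]
  ap[, AnnualRunoff := rgamma(n, 2, scale = 40)]
  ap[, AnnualDrainage := rgamma(n, 2, scale = 80)]
  ap[, AnnualGrossMiner := pmax(20, rnorm(n, 120, 20))]
  ap[, AnnualNlossTotal := rgamma(n, 2, scale = 15)]
  ap[, DOY_Sowing := pmin(366, pmax(1, round(rnorm(n, 125, 8))))]
  ap[, DOY_Harvest := pmin(366, pmax(1, round(rnorm(n, 290, 10))))]
  sw_base <- stats::plogis(rnorm(n, 0.3 + 0.3 * z_prcp, 0.4))
  for (m in c("Apr", "May", "Jun", "Jul", "Aug", "Sep", "Oct")) {
    ap[, (paste0("SW1m_", m)) := clamp01(sw_base + rnorm(n, 0, 0.05))]
    ap[, (paste0("SW15cm_", m)) := clamp01(sw_base + rnorm(n, 0, 0.08))]
  }
  ap[, WTatPlanting := pmax(100, rnorm(n, 1500, 400))]
  ap[, SW45_excess := clamp01(stats::plogis(-2 + 0.7 * z_prcp +
                                              rnorm(n, 0, 0.3)))]
  ap[, SW45_deficit := clamp01(stats::plogis(-1.5 - 0.8 * z_prcp +
                                               rnorm(n, 0, 0.3)))]
  data.table::setcolorder(ap, c("geoid", "year", apsim_cols()))
  ap[]
}

#' Inject the structured missingness the preprocessing stage must repair
#'
#' Blanks the planting-progress columns of one designated state before a
#' cutoff year (emulating a state whose survey series starts late) and a
#' random fraction of crop-model rows (emulating county-level simulation
#' gaps). The yield target is never blanked.
#'
#' @param panels named list with at least `planting` and `apsim` tables
#'   (as from [simulate_environment()] / [simulate_crop()]).
#' @param config a [scenario_config()].
#' @return the list with missingness applied.
#' @export
inject_missingness <- function(panels, config) {
  stopifnot(inherits(config, "yc_scenario"))
  rate <- config$missing$apsim_rate
  if (rate < 0 || rate > 1) stop_config("apsim rate must lie in [0, 1]")
  with_seed(derive_seed(config$seed, "missingness"), {
    pl <- data.table::copy(panels$planting)
    hit <- pl$state == config$missing$planting_state &
      pl$year < config$missing$planting_cutoff
    if (any(hit)) pl[hit, (planting_cols()) := NA_real_]
    panels$planting <- pl

    if (rate > 0) {
      ap <- data.table::copy(panels$apsim)
      blank <- runif(nrow(ap)) < rate
      if (any(blank)) ap[blank, (apsim_cols()) := NA_real_]
      panels$apsim <- ap
    }
    panels
  })
}

#' Generate a complete scenario in one call
#'
#' Chains [build_geography()], [simulate_environment()], [simulate_crop()]
#' and [inject_missingness()].
#'
#' @param config a [scenario_config()].
#' @return named list: `geography`, `weather`, `soil`, `planting`, `apsim`,
#'   `yield`.
#' @export
simulate_scenario <- function(config) {
  geo <- build_geography(config)
  env <- simulate_environment(geo, config$years, config)
  crop <- simulate_crop(env$weather, env$soil, env$planting, geo, config)
  panels <- c(list(geography = geo), env, crop)
  inject_missingness(panels, config)
}
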