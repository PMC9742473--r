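#' Scenario configuration for the synthetic Corn Belt generator
#'
#' Builds the configuration object consumed by [build_geography()],
#' [simulate_environment()], [simulate_crop()] and [inject_missingness()].
#' Defaults describe a small but structurally faithful US-Corn-Belt-style
#' panel: 12 states, 2 crop reporting districts (CRDs) per state, 3 counties
#' per CRD, calendar years 1984-2020, a genetic/management yield trend of
#' about +0.12 Mg/ha/yr, county yield noise of 0.5 Mg/ha, a crop-simulation
#' output block whose annual yield correlates with true yield at 0.82 (the
#' skill level typical of a regionally calibrated process model), planting
#' progress missing for one state before 2000, 5% of crop-simulation rows
#' missing, and a 27-county windstorm-style yield shock in 2020.
#'
#' @param n_states number of states.
#' @param crds_per_state CRDs per state.
#' @param counties_per_crd counties per CRD.
#' @param years integer vector of calendar years (used directly as the trend
#'   regressor).
#' @param state_codes optional character vector of 2-letter state codes;
#'   defaults to the 12 Corn Belt states, extended synthetically if needed.
#' @param trend list: `b1_mean`, `b1_sd` (Mg/ha per year), `base_mean`,
#'   `base_sd` (Mg/ha at `ref_year`), `ref_year`. The county intercept is
#'   `b0 = base - b1 * ref_year` so that `b0 + b1 * year` is a sensible yield.
#' @param weather_effects named numeric: Mg/ha per standard deviation of the
#'   summer precipitation total, summer maximum temperature and season
#'   growing-degree-day total.
#' @param soil_effects named numeric: Mg/ha per standard deviation of topsoil
#'   organic matter and plant-available water capacity.
#' @param apsim_fidelity correlation in `[0,1]` between the simulated crop
#'   model's `AnnualYield` and true (pre-shock) yield.
#' @param noise_sd county-year yield noise SD (Mg/ha).
#' @param cropland list `mean`, `conc`: Beta parameters (mean/concentration)
#'   of the county cropland ratio.
#' @param low_cropland list `factor`, `threshold`: counties whose cropland
#'   ratio falls below `threshold` get `noise_sd * factor`; `factor = 1`
#'   disables the mechanism.
#' @param missing list `planting_state` (2-letter code or NULL for the
#'   last state), `planting_cutoff` (planting rows of that state before this
#'   year are blanked), `apsim_rate` (fraction of crop-model rows blanked).
#' @param shock list `year`, `n_counties`, `magnitude` (Mg/ha reduction),
#'   `state` (restrict shocked counties to one state, or NULL for any);
#'   `n_counties = 0` disables the shock.
#' @param seed integer; fixes all generator randomness.
#' @return A `yc_scenario` list with validated fields.
#' @export
scenario_config <- function(n_states = 12, crds_per_state = 2,
                            counties_per_crd = 3, years = 1984:2020,
                            state_codes = NULL,
                            trend = list(),
                            weather_effects = c(prcp_summer = 0.3,
                                                tmax_summer = -0.25,
                                                gdd_season = 0.15),
                            soil_effects = c(om_top = 0.2, paw_top = 0.15),
                            apsim_fidelity = 0.82,
                            noise_sd = 0.5,
                            cropland = list(mean = 0.45, conc = 8),
                            low_cropland = list(factor = 1, threshold = 0.3),
                            missing = list(),
                            shock = list(),
                            seed = 0L) {
  trend <- utils::modifyList(
    list(b1_mean = 0.12, b1_sd = 0.02, base_mean = 8.5, base_sd = 1.0,
         ref_year = 2002), trend)
  missing <- utils::modifyList(
    list(planting_state = NULL, planting_cutoff = 2000, apsim_rate = 0.05),
    missing)
  shock <- utils::modifyList(
    list(year = 2020, n_counties = 27, magnitude = 3.0, state = NULL), shock)

  if (any(c(n_states, crds_per_state, counties_per_crd) < 1))
    stop_config("state/CRD/county counts must all be >= 1")
  if (length(years) == 0)
    stop_config("empty year range")
  if (apsim_fidelity < 0 || apsim_fidelity > 1)
    stop_config("apsim_fidelity must lie in [0, 1]")
  if (noise_sd < 0 || trend$b1_sd < 0 || trend$base_sd < 0)
    stop_config("all SDs must be >= 0")
  if (missing$apsim_rate < 0 || missing$apsim_rate > 1)
    stop_config("apsim missingness rate must lie in [0, 1]")
  if (cropland$mean <= 0 || cropland$mean >= 1 || cropland$conc <= 0)
    stop_config("cropland mean must be in (0,1), concentration > 0")
  if (shock$n_counties < 0)
    stop_config("shock n_counties must be >= 0")

  if (is.null(state_codes)) {
    belt <- c("IL", "IN", "IA", "KS", "MI", "MN", "MO", "NE", "ND", "OH",
              "SD", "WI")
    state_codes <- if (n_states <= length(belt)) belt[seq_len(n_states)] else {
      extra <- apply(expand.grid(LETTERS, LETTERS)[, 2:1], 1, paste0,
                     collapse = "")
      unique(c(belt, extra))[seq_len(n_states)]
    }
  }
  if (length(state_codes) != n_states || anyDuplicated(state_codes))
    stop_config("state_codes must be ", n_states, " unique 2-letter codes")
  if (is.null(missing$planting_state))
    missing$planting_state <- if ("ND" %in% state_codes) "ND" else
      state_codes[n_states]

  structure(list(
    n_states = as.integer(n_states),
    crds_per_state = as.integer(crds_per_state),
    counties_per_crd = as.integer(counties_per_crd),
    years = as.integer(sort(years)), state_codes = state_codes,
    trend = trend, weather_effects = weather_effects,
    soil_effects = soil_effects, apsim_fidelity = apsim_fidelity,
    noise_sd = noise_sd, cropland = cropland, low_cropland = low_cropland,
    missing = missing, shock = shock, seed = as.integer(seed)
  ), class = "yc_scenario")
}

#' Read or write a scenario configuration as YAML
#'
#' @param config a `yc_scenario` object.
#' @param path file path.
#' @return `read_scenario_yaml()` returns a validated `yc_scenario`.
#' @export
write_scenario_yaml <- function(config, path) {
  stopifnot(inherits(config, "yc_scenario"))
  raw <- unclass(config)
  raw$weather_effects <- as.list(raw$weather_effects)  # keep YAML maps
  raw$soil_effects <- as.list(raw$soil_effects)
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$weather_effects <- unlist(raw$weather_effects)
  raw$soil_effects <- unlist(raw$soil_effects)
  do.call(scenario_config, raw)
}

# Schema vocabulary shared by the generator and preprocessing ----------------

wx_vars <- c("rad", "prcp", "tmin", "tmax", "gdd")

weekly_weather_cols <- function() {
  as.vector(t(outer(wx_vars, sprintf("wk%02d", 1:52),
                    function(v, w) paste0("wx_", v, "_", w))))
}

# 33 auxiliary seasonal/annual weather summaries (kept fixed so that the
# weather block has exactly 260 + 33 = 293 columns).
aux_weather_cols <- function() {
  c(sprintf("aux_tavg_m%02d", 1:12), sprintf("aux_prcp_m%02d", 1:12),
    sprintf("aux_rad_q%d", 1:4),
    c("aux_rad_tot", "aux_prcp_tot", "aux_gdd_tot", "aux_tmin_mean",
      "aux_tmax_mean"))
}

soil_props <- c("om", "sand", "clay", "ph", "bd", "wp", "fc", "sat", "ksat",
                "paw")

soil_cols <- function() {
  as.vector(t(outer(soil_props, sprintf("d%02d", 1:10),
                    function(p, d) paste0("soil_", p, "_", d))))
}

planting_cols <- function() sprintf("plant_wk%02d", 1:52)

apsim_cols <- function() {
  c("AnnualYield", "AnnualBiomass", "AnnualRootD", "DOY_Flowering",
    "DOY_Maturity", "AnnualLaiMax", "AnnualET", "MaizeTranspiration",
    "AnnualNupt", "AnnualGrainlNupt", "AvgDroughtStress", "AvgExcessWStress",
    "AvgNStress", "AnnualAvgWT", "AnnualRunoff", "AnnualDrainage",
    "AnnualGrossMiner", "AnnualNlossTotal", "DOY_Sowing", "DOY_Harvest",
    sprintf("SW1m_%s", c("Apr", "May", "Jun", "Jul", "Aug", "Sep", "Oct")),
    sprintf("SW15cm_%s", c("Apr", "May", "Jun", "Jul", "Aug", "Sep", "Oct")),
    "WTatPlanting", "SW45_excess", "SW45_deficit")
}

# weeks belonging to each of the 12 "months" (4-4-5 pattern, sums to 52)
month_of_week <- function() rep(1:12, c(4, 4, 5, 4, 4, 5, 4, 4, 5, 4, 4, 5))
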