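# synthetic panel generator: hierarchy, schemas, invariants, determinism

test_that("geography has the product-of-counts shape and is reproducible", {
  sc <- scenario_config(n_states = 2, crds_per_state = 2,
                        counties_per_crd = 3, seed = 11)
  g <- build_geography(sc)
  expect_equal(nrow(g), 12)
  expect_equal(length(unique(g$geoid)), 12)
  expect_true(all(nchar(g$geoid) == 5))
  expect_true(all(g$cropland_ratio >= 0 & g$cropland_ratio <= 1))
  # every county in exactly one CRD and state
  expect_equal(anyDuplicated(g$geoid), 0)
  expect_true(all(table(g$crd) == 3))
  expect_identical(g, build_geography(sc))
  expect_error(scenario_config(n_states = 0), "counts")
})

test_that("cropland ratio matches the configured Beta distribution", {
  # Monte-Carlo: mean over ~10,000 counties within 3 SE of the Beta mean
  sc <- scenario_config(n_states = 25, crds_per_state = 20,
                        counties_per_crd = 20,
                        state_codes = NULL, seed = 5)
  g <- build_geography(sc)
  m <- sc$cropland$mean; k <- sc$cropland$conc
  se <- sqrt(m * (1 - m) / (1 + k)) / sqrt(nrow(g))
  expect_gt(nrow(g), 9999)
  expect_lt(abs(mean(g$cropland_ratio) - m), 3 * se)
})

test_that("environment schemas and physical invariants hold", {
  panels <- default_panels()
  w <- panels$weather
  expect_equal(ncol(w) - 2, 293)           # weekly + auxiliary weather block
  expect_equal(ncol(panels$soil) - 1, 100)
  expect_equal(ncol(panels$planting) - 2, 52)
  expect_equal(ncol(panels$apsim) - 2, 37)

  for (wk in sprintf("%02d", 1:52)) {
    expect_true(all(w[[paste0("wx_tmax_wk", wk)]] >=
                      w[[paste0("wx_tmin_wk", wk)]]))
    expect_true(all(w[[paste0("wx_prcp_wk", wk)]] >= 0))
    expect_true(all(w[[paste0("wx_rad_wk", wk)]] >= 0))
    expect_true(all(w[[paste0("wx_gdd_wk", wk)]] >= 0))
  }

  # planting cumulative curves nondecreasing, in [0, 100]
  pl <- as.matrix(na.omit(panels$planting)[, -(1:2)])
  expect_true(all(pl >= 0 & pl <= 100))
  expect_true(all(diff(t(pl)) >= 0))

  # soil: texture and water-retention ordering per layer, static by design
  s <- panels$soil
  for (d in sprintf("%02d", 1:10)) {
    expect_true(all(s[[paste0("soil_sand_d", d)]] +
                      s[[paste0("soil_clay_d", d)]] <= 100))
    expect_true(all(s[[paste0("soil_wp_d", d)]] <=
                      s[[paste0("soil_fc_d", d)]]))
    expect_true(all(s[[paste0("soil_fc_d", d)]] <=
                      s[[paste0("soil_sat_d", d)]]))
  }
})

test_that("crop-model outputs respect their physical ranges", {
  ap <- na.omit(default_panels()$apsim)
  for (cl in c("AvgDroughtStress", "AvgExcessWStress", "AvgNStress",
               "SW1m_Jul", "SW15cm_Jul", "SW45_excess", "SW45_deficit"))
    expect_true(all(ap[[cl]] >= 0 & ap[[cl]] <= 1), label = cl)
  for (cl in c("DOY_Flowering", "DOY_Maturity", "DOY_Sowing", "DOY_Harvest"))
    expect_true(all(ap[[cl]] >= 1 & ap[[cl]] <= 366), label = cl)
  expect_true(all(ap$AnnualYield >= 0))
})

test_that("county weekly tmax means track the configured state climatology", {
  # Monte-Carlo: expected weekly tmax mean is the state's base temperature
  # plus the (zero-mean) seasonal cycle plus the +5 half-spread offset
  sc <- scenario_config(n_states = 2, crds_per_state = 2,
                        counties_per_crd = 10, years = 1984:2020,
                        shock = list(n_counties = 0), seed = 3)
  g <- build_geography(sc)
  env <- simulate_environment(g, sc$years, sc)
  wcols <- sprintf("wx_tmax_wk%02d", 1:52)
  tmax_mean <- rowMeans(as.matrix(env$weather[, wcols, with = FALSE]))
  st <- g$state[match(env$weather$geoid, g$geoid)]
  grad <- (match(st, sc$state_codes) - 1) / (sc$n_states - 1) * 2 - 1
  expected <- 10 - 3 * grad + 5
  # SE: state-year anomaly 1.2/sqrt(years), county base 0.6/sqrt(counties),
  # weekly noise negligible after averaging 52 x years x counties values
  for (s in sc$state_codes) {
    i <- st == s
    se <- sqrt(1.2^2 / length(unique(env$weather$year[i])) +
                 0.6^2 / length(unique(env$weather$geoid[i])))
    expect_lt(abs(mean(tmax_mean[i]) - mean(expected[i])), 3 * se)
  }
})

test_that("crop simulation: fidelity, shock count, trend recovery", {
  # degenerate fidelity: crop-model yield is true yield exactly
  sc1 <- scenario_config(n_states = 2, crds_per_state = 1,
                         counties_per_crd = 3, apsim_fidelity = 1,
                         noise_sd = 0, shock = list(n_counties = 0),
                         missing = list(apsim_rate = 0), seed = 2)
  p1 <- simulate_scenario(sc1)
  expect_equal(cor(p1$apsim$AnnualYield / 1000, p1$yield$yield), 1,
               tolerance = 1e-12)

  # the stated shock: exactly 27 flagged county-years, all at the shock year
  py <- default_panels()$yield
  expect_equal(sum(py$shock_flag), 27)
  expect_true(all(py[shock_flag == TRUE, year] == 2020))

  # noise-free, effect-free panel: OLS on year returns the trend exactly
  sc0 <- scenario_config(n_states = 2, crds_per_state = 1,
                         counties_per_crd = 3, noise_sd = 0,
                         weather_effects = c(prcp_summer = 0,
                                             tmax_summer = 0,
                                             gdd_season = 0),
                         soil_effects = c(om_top = 0, paw_top = 0),
                         shock = list(n_counties = 0), seed = 4)
  p0 <- simulate_scenario(sc0)
  tr <- compute_trend_feature(p0$yield, sc0$years)
  fitted <- predict_trend(tr, p0$yield$geoid, p0$yield$year)
  expect_equal(fitted, p0$yield$yield, tolerance = 1e-10)

  # noisy panel: mean recovered slope within 3 SE of the configured slope
  scn <- scenario_config(n_states = 6, crds_per_state = 2,
                         counties_per_crd = 3, noise_sd = 0.5,
                         weather_effects = c(prcp_summer = 0,
                                             tmax_summer = 0,
                                             gdd_season = 0),
                         soil_effects = c(om_top = 0, paw_top = 0),
                         shock = list(n_counties = 0), seed = 6)
  pn <- simulate_scenario(scn)
  trn <- compute_trend_feature(pn$yield, scn$years)
  sxx <- sum((scn$years - mean(scn$years))^2)
  se_b1 <- sqrt(scn$trend$b1_sd^2 + 0.5^2 / sxx) / sqrt(nrow(trn))
  expect_lt(abs(mean(trn$b1) - scn$trend$b1_mean), 3 * se_b1)
})

test_that("missingness injection follows the configured structure", {
  panels <- default_panels()
  sc <- scenario_config(seed = 0)
  nd <- sc$missing$planting_state
  miss <- panels$planting[state == nd & is.na(plant_wk20), year]
  expect_equal(sort(miss), 1984:1999)      # 16 years before the 2000 cutoff
  expect_false(anyNA(panels$planting[state != nd]))
  expect_false(anyNA(panels$yield$yield))  # target never blanked

  # rate 0 is the identity
  sc0 <- scenario_config(n_states = 2, crds_per_state = 1,
                         counties_per_crd = 2,
                         missing = list(apsim_rate = 0),
                         shock = list(n_counties = 0), seed = 1)
  g <- build_geography(sc0)
  env <- simulate_environment(g, sc0$years, sc0)
  crop <- simulate_crop(env$weather, env$soil, env$planting, g, sc0)
  out <- inject_missingness(c(list(geography = g), env, crop), sc0)
  expect_identical(out$apsim, crop$apsim)

  # binomial check: rate 0.1 over ~10,000 rows lands in [0.08, 0.12]
  scb <- scenario_config(n_states = 12, crds_per_state = 3,
                         counties_per_crd = 8, years = 1984:2020,
                         missing = list(apsim_rate = 0.1), seed = 9)
  pb <- simulate_scenario(scb)
  frac <- mean(is.na(pb$apsim$AnnualYield))
  expect_gt(nrow(pb$apsim), 10000)
  expect_true(frac >= 0.08 && frac <= 0.12)
  expect_error(
    simulate_scenario(scenario_config(missing = list(apsim_rate = 1.5))),
    "rate")
})

test_that("the generator is bit-identical under a repeated seed", {
  sc <- tiny_scenario(seed = 42)
  expect_identical(simulate_scenario(sc), simulate_scenario(sc))
})

test_that("CSV round-trip preserves geoids and values", {
  sc <- scenario_config(n_states = 2, crds_per_state = 1,
                        counties_per_crd = 2, years = 2018:2020,
                        shock = list(n_counties = 0), seed = 8)
  panels <- simulate_scenario(sc)
  dir <- withr::local_tempdir()
  write_scenario_csvs(panels, dir)
  back <- read_scenario_csvs(dir)
  expect_identical(back$geography$geoid, panels$geography$geoid)
  expect_equal(back$yield$yield, panels$yield$yield, tolerance = 1e-12)
  expect_equal(dim(back$weather), dim(panels$weather))
})
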