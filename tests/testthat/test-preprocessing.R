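# merge, imputation rules, quarterly features, yield trend

test_that("merge is row-conservative on the yield reference", {
  panels <- default_panels()
  panel <- merge_sources(panels$yield, panels$weather, panels$soil,
                         panels$planting, panels$apsim, panels$geography)
  expect_equal(nrow(panel), nrow(panels$yield))   # 72 counties x 37 years

  # soil columns are identical across years within a county
  g1 <- panel$geoid[1]
  expect_equal(panel[geoid == g1 & year == 1984, soil_clay_d01],
               panel[geoid == g1 & year == 2020, soil_clay_d01])

  # a county-year present in weather but absent in yields is dropped
  short_yields <- panels$yield[year < 2020]
  p2 <- merge_sources(short_yields, panels$weather, panels$soil,
                      panels$planting, panels$apsim, panels$geography)
  expect_equal(nrow(p2), nrow(short_yields))
  expect_false(2020 %in% p2$year)

  # integrity errors
  dup <- rbind(panels$yield, panels$yield[1])
  expect_error(merge_sources(dup, panels$weather, panels$soil,
                             panels$planting, panels$apsim,
                             panels$geography), "integrity")
  orphan <- data.table::copy(panels$yield)
  orphan[1, geoid := "99999"]
  expect_error(merge_sources(orphan, panels$weather, panels$soil,
                             panels$planting, panels$apsim,
                             panels$geography), "join error")
})

test_that("imputation follows the state-mean and county-median rules", {
  # planting: week-n gap takes the state's mean of observed week-n values
  panel <- data.table::data.table(
    geoid = c("00001", "00001", "00001", "00001"),
    year = 2001:2004, state = "IA",
    plant_wk20 = c(10, 20, 30, NA),
    AnnualET = c(400, 500, 10000, NA))
  out <- impute_missing(panel)
  expect_equal(out$plant_wk20[4], 20)
  # crop model: county median damps the outlier (median, not mean)
  expect_equal(out$AnnualET[4], 500)
  expect_equal(attr(out, "imputed_cells"), 2L)

  # identity on complete panels, and idempotence
  full <- impute_missing(out)
  expect_equal(full, out, ignore_attr = TRUE)

  # county with zero observations falls back to state, then global median
  p2 <- data.table::data.table(
    geoid = c("00001", "00001", "00002"), year = c(2001, 2002, 2001),
    state = c("IA", "IA", "IA"),
    AnnualET = c(400, 600, NA))
  expect_equal(impute_missing(p2)$AnnualET[3], 500)
})

test_that("imputation clears the generator's structured gaps", {
  panels <- default_panels()
  pre <- preprocess_panels(panels, train_years = 1984:2017)
  expect_equal(sum(is.na(pre$panel)), 0)
  expect_gt(attr(impute_missing(merge_sources(
    panels$yield, panels$weather, panels$soil, panels$planting,
    panels$apsim, panels$geography)), "imputed_cells"), 0)
})

test_that("quarterly features: sums, means, and column count", {
  panels <- default_panels()
  panel <- merge_sources(panels$yield, panels$weather, panels$soil,
                         panels$planting, panels$apsim, panels$geography)

  # constant-week arithmetic on a doctored row
  doctored <- data.table::copy(panel)
  for (wk in sprintf("%02d", 1:13))
    doctored[1, (paste0("wx_prcp_wk", wk)) := 2]
  for (wk in sprintf("%02d", 14:26))
    doctored[1, (paste0("wx_tmax_wk", wk)) := 30]
  q <- add_quarterly_features(doctored)
  expect_equal(q$wxq_prcp_q1[1], 26)
  expect_equal(q$wxq_tmax_q2[1], 30)
  expect_equal(ncol(q), ncol(panel) + 20)

  # exact aggregation identity on every row
  q2 <- add_quarterly_features(panel)
  wk3 <- sprintf("wx_gdd_wk%02d", 27:39)
  expect_equal(q2$wxq_gdd_q3,
               rowSums(as.matrix(panel[, wk3, with = FALSE])))
  wk1 <- sprintf("wx_tmin_wk%02d", 1:13)
  expect_equal(q2$wxq_tmin_q1,
               rowMeans(as.matrix(panel[, wk1, with = FALSE])))

  expect_error(add_quarterly_features(panel[, 1:20, with = FALSE]),
               "schema")
})

test_that("trend fit: exact line, arithmetic, and the state fallback", {
  yrs <- 2000:2010
  y <- data.table::data.table(geoid = "00001", year = yrs,
                              yield = 2 + 0.1 * yrs)
  tr <- compute_trend_feature(y, yrs)
  expect_equal(tr$b0, 2, tolerance = 1e-10)
  expect_equal(tr$b1, 0.1, tolerance = 1e-12)

  # evaluating the line: b0 = -200, b1 = 0.105 at 2018 gives 11.89
  fake <- structure(
    data.table::data.table(geoid = "00001", b0 = -200, b1 = 0.105,
                           n_train = 10L, source = "county"),
    class = c("yc_trend", "data.table", "data.frame"))
  expect_equal(predict_trend(fake, "00001", 2018), 11.89)

  # a county with < 2 training years inherits the state fit
  y2 <- rbind(y, data.table::data.table(geoid = "00002", year = 2010,
                                        yield = 3.2))
  geo <- data.table::data.table(geoid = c("00001", "00002"),
                                state = "IA", crd = "IA-01",
                                cropland_ratio = 0.5)
  expect_message(tr2 <- compute_trend_feature(y2, yrs, geo), "state")
  expect_equal(tr2[geoid == "00002", source], "state")
  expect_error(compute_trend_feature(
    data.table::data.table(geoid = "00001", year = c(2000, 2000),
                           yield = c(1, 2)), 2000), "singular")
})

test_that("trend is fitted on training years only (leakage guard)", {
  panels <- default_panels()
  tr_a <- compute_trend_feature(panels$yield, 1984:2017, panels$geography)
  corrupted <- data.table::copy(panels$yield)
  corrupted[year >= 2018, yield := yield * 10]
  tr_b <- compute_trend_feature(corrupted, 1984:2017, panels$geography)
  expect_identical(tr_a$b0, tr_b$b0)
  expect_identical(tr_a$b1, tr_b$b1)
})
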