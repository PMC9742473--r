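# temporal split, tuned base learners, out-of-fold prediction matrices

test_that("temporal split is a year-ahead partition", {
  panel <- data.table::data.table(geoid = "00001", year = 1984:2020, x = 0,
                                  yield = 1)
  sp <- temporal_split(panel, 2018)
  expect_equal(range(sp$train$year), c(1984, 2017))
  expect_equal(unique(sp$test$year), 2018)
  # partition property: union is exactly the rows up to the test year
  expect_equal(sort(c(sp$train$year, sp$test$year)),
               panel[year <= 2018, sort(year)])
  expect_error(temporal_split(panel, 1984), "empty-train")
  expect_error(temporal_split(panel, 1900), "not present")
})

test_that("the linear family is plain least squares, lasso converges to it", {
  panel <- signal_panel(n_counties = 30, years = 2001:2010, n_signal = 3,
                        n_noise = 2, seed = 5)
  feats <- sprintf("f%02d", 1:5)
  m_lin <- tune_and_fit(learner_spec("linear"), panel, feats, seed = 1)
  ref <- lm(yield ~ ., data = panel[, c("yield", feats), with = FALSE])
  expect_equal(unname(m_lin$object$coef), unname(coef(ref)),
               tolerance = 1e-8)

  # l1 penalty -> 0: coefficients converge to the least-squares fit
  m_l0 <- tune_and_fit(learner_spec("lasso", params = list(lambda = 1e-7),
                                    tune = FALSE),
                       panel, feats, seed = 1)
  cf <- as.numeric(coef(m_l0$object, s = 1e-7))
  expect_equal(cf, unname(coef(ref)), tolerance = 1e-3)
})

test_that("tuning is deterministic and improves on a bad fixed choice", {
  panel <- signal_panel(n_counties = 25, years = 2001:2010, n_signal = 3,
                        n_noise = 10, seed = 6)
  feats <- sprintf("f%02d", 1:13)
  spec <- learner_spec("lasso", n_iter = 8, n_folds = 4)
  m1 <- tune_and_fit(spec, panel, feats, seed = 3)
  m2 <- tune_and_fit(spec, panel, feats, seed = 3)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$cv_mse, m2$cv_mse)

  bad <- yieldcast:::cv_mse("lasso", yieldcast:::panel_matrix(panel, feats),
                            panel$yield, list(lambda = 9), 4, 3)
  expect_lt(m1$cv_mse, bad)
})

test_that("prediction matrices have the contracted shape and alignment", {
  panel <- signal_panel(n_counties = 20, years = 2001:2011, n_signal = 3,
                        n_noise = 4, seed = 7)
  feats <- sprintf("f%02d", 1:7)
  sp <- temporal_split(panel, 2011)
  models <- list(
    linear = tune_and_fit(learner_spec("linear"), sp$train, feats, seed = 1),
    lasso = tune_and_fit(learner_spec("lasso", tune = FALSE), sp$train,
                         feats, seed = 1),
    rf = tune_and_fit(learner_spec("rf", tune = FALSE,
                                   params = list(ntree = 40)),
                      sp$train, feats, seed = 1))
  cp <- collect_predictions(models, sp$train, sp$test, feats,
                            n_folds = 5, seed = 2)
  expect_identical(attr(cp$train, "models"), names(models))
  expect_equal(ncol(yieldcast::pm_predictions(cp$train)), 3)
  expect_false(anyNA(yieldcast::pm_predictions(cp$train)))
  expect_identical(cp$test[, paste(geoid, year)],
                   sp$test[, paste(geoid, year)])
  expect_identical(unique(cp$train$role), "train-out-of-fold")
  expect_identical(unique(cp$test$role), "test")
})

test_that("a memorizing probe separates in-sample from out-of-fold", {
  panel <- signal_panel(n_counties = 15, years = 2001:2008, n_signal = 2,
                        n_noise = 2, seed = 8)
  feats <- sprintf("f%02d", 1:4)
  sp <- temporal_split(panel, 2008)
  probe <- yieldcast:::fit_family(
    "knn1", yieldcast:::panel_matrix(sp$train, feats), sp$train$yield,
    list(), 1)
  ins <- collect_predictions(list(probe = probe), sp$train, sp$test, feats,
                             mode = "in-sample", seed = 1)
  oof <- collect_predictions(list(probe = probe), sp$train, sp$test, feats,
                             mode = "out-of-fold", n_folds = 5, seed = 1)
  expect_equal(ins$train$probe, ins$train$y, tolerance = 1e-12)
  expect_gt(mean((oof$train$probe - oof$train$y)^2), 0)
})

test_that("test-year rows never influence fitting (leakage guard)", {
  sc <- tiny_scenario(seed = 13)
  panels_a <- simulate_scenario(sc)
  panels_b <- lapply(panels_a, data.table::copy)
  panels_b$yield[year == 2020, yield := yield * 5]   # corrupt test year

  fit_under <- function(panels) {
    pre <- preprocess_panels(panels, train_years = 1996:2019)
    sp <- temporal_split(pre$panel, 2020)
    feats <- c("yield_trend", "AnnualYield", "wxq_prcp_q3", "soil_om_d01")
    m <- tune_and_fit(learner_spec("gbA", tune = FALSE,
                                   params = list(ntree = 30)),
                      sp$train, feats, seed = 5)
    predict(m, yieldcast:::panel_matrix(sp$test, feats))
  }
  expect_identical(fit_under(panels_a), fit_under(panels_b))
})

test_that("fold bookkeeping and error paths", {
  expect_error(yieldcast:::make_folds(5, 10, 1), "invalid fold")
  panel <- signal_panel(n_counties = 4, years = 2001:2003, n_signal = 1,
                        n_noise = 1, seed = 9)
  sp <- temporal_split(panel, 2003)
  m <- tune_and_fit(learner_spec("linear"), sp$train, c("f01", "f02"),
                    seed = 1)
  expect_error(collect_predictions(list(m = m), sp$train, sp$test,
                                   c("f01", "f02"), n_folds = 5, seed = 1),
               "fold")
  expect_error(learner_spec("rf", n_folds = 1), "budget")
  expect_error(tune_and_fit(learner_spec("linear"), sp$train,
                            c("f01", "nope"), seed = 1), "absent")
})
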