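Package: yieldcast
Title: County-Scale Maize Yield Prediction with Crop-Model-Coupled Ensembles
Version: 0.1.0
Authors@R:
    person("yieldcast", "developers", email = "yieldcast@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for county-by-year maize yield prediction in
    the style used across the US Corn Belt: a synthetic panel generator that
    emulates weekly weather, layered soil, state planting progress, crop
    simulation (APSIM-style) outputs and county yields with a realistic
    trend and spatial hierarchy; preprocessing with reference-join merging,
    rule-based imputation, quarterly weather features and a per-county yield
    trend; two-stage feature selection (expert week windows, then
    permutation importance under a random forest); five base learners
    (linear, lasso, random forest and two gradient-boosting variants) tuned
    by Bayesian search under year-ahead temporal splits; a constrained
    optimized-weight ensemble on the weight simplex; and evaluation with
    RMSE, relative RMSE, mean bias error and R-squared aggregated by county,
    district, state and year, plus error-covariate correlation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    glmnet,
    jsonlite,
    nloptr,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
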