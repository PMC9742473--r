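---
title: "Methods: crop-model-coupled ensemble yield prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crop-model-coupled ensemble yield prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the modelling approach

County-scale maize yield prediction in the US Corn Belt is usually attacked
either with process-based crop simulators (transparent, physiology-driven,
costly to calibrate) or with machine-learning models trained on historical
panels (cheap to deploy, opaque). `yieldcast` implements the hybrid
strategy: outputs of a crop simulator are fed to machine-learning models as
additional engineered features, and the final prediction is a *stacked
ensemble* whose weights are optimized under constraints.

The pipeline, per held-out year:

1. **Merge** weekly weather (293 columns), layered soil (10 properties x 10
   depths), state-level weekly cumulative planting progress (52 columns),
   37 crop-simulation output variables and observed county yields onto the
   yield table, keyed by the 5-digit county GEOID and year.
2. **Impute**: planting gaps take the state mean of the same week across
   observed years; crop-model gaps take the county median (median because
   it damps simulation outliers), falling back to state then global median
   where a county has no observations at all.
3. **Feature construction**: 20 quarterly weather aggregates (sums of
   precipitation, radiation and growing degree days; means of min/max
   temperature over 13-week blocks) and a per-county *yield trend*
   `y = b0 + b1 * year`, an ordinary-least-squares line capturing genetic
   and management progress.
4. **Two-stage feature selection**: an expert filter keeps weather weeks
   16-43 and planting weeks 12-29 (outside those windows the columns carry
   no information about the current crop) plus all soil, quarterly,
   crop-model and trend columns; permutation importance under a random
   forest then keeps the top 100.
5. **Five base learners** — linear regression, lasso, random forest and
   two gradient-boosting variants — tuned by Bayesian search (40
   evaluations, 10-fold CV by default) on the training years only.
6. **Ensembles**: an equal-weight average, and an optimized-weight
   ensemble solving

   minimize   sqrt( (1/n) * sum_i ( y_i - sum_j w_j yhat_ij )^2 )
   subject to sum_j w_j = 1,  w_j >= 0,
              ensemble MSE <= MSE of every base learner j,

   fitted on *out-of-fold* training predictions.
7. **Evaluation**: RMSE, relative RMSE (percent of the observed mean),
   mean bias error and R-squared, overall and by county / crop reporting
   district (CRD) / state / year, after excluding storm-shocked
   county-years from the evaluation set only; plus a Pearson analysis
   correlating county RMSE with soil and weather covariates.

## The synthetic stated world

Real NASS/SSURGO/mesonet/simulator extracts are not shipped; a generator
reproduces their joint structure so every stage is exercisable offline.
Defaults, chosen once:

| parameter | default | unit | why |
|---|---|---|---|
| panel | 12 states x 2 CRDs x 3 counties, 1984-2020 | — | smallest panel with a full hierarchy; 12 Corn Belt state codes |
| trend slope `b1` | N(0.12, 0.02) | Mg/ha/yr | the long-run US maize genetic/management gain |
| base yield at 2002 | N(8.5, 1.0) | Mg/ha | puts 2018-2020 county means near 10.5 Mg/ha and mid-1980s means near 6.5 |
| yield noise | 0.5 | Mg/ha | county-year variability left after trend and weather |
| weather effects | +0.30 summer precip, -0.25 summer tmax, +0.15 season GDD | Mg/ha per SD | linear climate response with realistic signs |
| soil effects | +0.20 organic matter, +0.15 plant-available water | Mg/ha per SD | fertility/water-holding gradients |
| crop-model fidelity | 0.82 | correlation | a regionally calibrated simulator explaining about two-thirds of yield variance (R^2 ~ 0.67) |
| planting missingness | one state blanked before 2000 | — | a state whose weekly survey series starts late |
| crop-model gaps | 5% of county-years | — | county/grid granularity mismatches |
| shock | 27 counties, -3 Mg/ha, 2020 | — | a derecho-style windstorm hitting a contiguous season |
| cropland ratio | Beta(mean 0.45, concentration 8) | — | Corn Belt county cropland shares |

Counties of a state share state-year weather anomalies, so cross-sectional
learning is possible and regional errors correlate — the feature the
reliability analysis needs. An optional mechanism inflates yield noise in
counties below a cropland-ratio threshold, reproducing the situation where
sparse-cropland areas are harder to predict.

What the generator does **not** emulate: spatial autocorrelation finer
than the state level, non-linear or threshold climate responses, yield
measurement error distinct from process noise, real soil geography, and
weather persistence across weeks. A green test suite therefore establishes
that the pipeline's machinery is correct on a panel with this structure,
not that any accuracy level carries over to real data.

## Numerical and design choices

* **Trend leakage.** The trend is fit on training years only and
  extrapolated to the test year; refitting with test-year yields present
  must not change the coefficients (guarded by test). Counties with fewer
  than two training observations inherit the pooled state fit.
* **Quarters** are the four 13-week blocks — deterministic and evenly
  covering the year; the choice is a convention, not an estimate.
* **Out-of-fold stacking.** Weights fitted on in-sample training
  predictions concentrate on the most overfit learner; out-of-fold
  predictions (each row predicted by a refit that never saw its fold) are
  the default. Fold assignment is a seeded uniform permutation of rows,
  deliberately ignoring year so every fold sees all eras.
* **Root vs squared objective.** Minimizing RMSE and MSE over the same
  feasible set share their argmin (the root is monotone); the root is used
  because its scale matches the observations and conditions the search
  better on large panels. The equivalence is asserted as an invariant.
* **Feasibility of the dominance constraint.** The vertex putting all
  weight on the training-best base model satisfies every constraint, so
  the feasible set is never empty; SLSQP is multi-started from the
  equal-weight point and all vertices, and falls back to the best vertex
  (with a warning) if no start converges. Weights driven below zero by
  round-off (tolerance 1e-10) are clipped and the vector renormalized. A
  brute-force simplex-lattice oracle (k <= 4) verifies the solver.
* **Ties** in importance ranking and top-k selection break by
  lexicographic column name, so selection is stable across platforms.
* **R-squared** is `1 - RSS/TSS`, unclamped; it may be negative on
  held-out years. Relative RMSE and R-squared are reported `NA` with a
  warning in scopes with zero-mean or zero-variance truth (e.g. singleton
  county-years).
* **"Summer"** covariates use weeks 27-39 and "annual" all 52 weeks; the
  windows are documented configuration, not estimates.
* **Tree learners.** The forest and both boosting families run on an
  in-package histogram-based CART (quantile binning to at most 64 bins,
  best-first growth). A per-leaf depth cap gives the classical depth-wise
  boosting variant (`gbA`), a leaf-count cap the leaf-wise variant
  (`gbB`); with only the depth cap binding, best-first growth reproduces
  the classical recursive tree. Binned split search makes the default
  budgets tractable on one CPU.
* **Bayesian tuning** is a small Gaussian-process surrogate (RBF kernel on
  unit-scaled parameters, fixed length-scale 0.25, nugget 1e-6) with
  expected-improvement acquisition over a seeded candidate set. Search
  spaces: lasso penalty log-uniform [1e-4, 10]; forest trees 100-500,
  depth 3-20, feature fraction 0.2-1; boosting trees 100-1000, learning
  rate log-uniform [0.005, 0.3], depth 3-10 or leaves 8-64, row subsample
  0.5-1. These are conventional ranges. The selection forest's tree count
  may instead be grid-searched over {100, 200, 300, 500} under 10-fold
  CV; 300 trees is the pinned default when tuning is off.
* **Hyperparameters are re-tuned per test year** (rolling origin). This
  matches the year-ahead protocol; reusing one tuned configuration across
  years is the cheaper alternative the runner deliberately does not take.
* **Determinism.** One root seed; every stochastic stage derives its own
  stream from it, and reruns with the same configuration are
  bit-identical.

## Scaled-down budgets in the tests

The documented defaults (300-tree selection forest with 10 shuffle
repeats, 40-evaluation Bayesian search with 10-fold CV, 10-fold stacking)
are what a production run uses. The shipped tests and the acceptance
script reduce tree counts, repeats and folds — each reduction is visible
in the test's configuration — because the criteria they check are
structural counts, closed-form identities, constraint satisfaction and
directional effects, none of which depend on the budget. Generator
parameters (trend, noise, fidelity, shock size) are never scaled.

## Known limitations

* The impurity (split-gain) importance is exposed only as a diagnostic
  column; selection always uses permutation importance.
* The weight vector is global per training set — no per-region weights,
  no regularization of weights, no Bayesian model averaging.
* No neural-network baselines, no choropleth rendering (tabular outputs
  only), and no physical crop simulation: the crop-model block is a
  statistical stand-in whose fidelity is a dial, which is precisely what
  makes the with/without-crop-model comparison testable.
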