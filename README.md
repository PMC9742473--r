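# yieldcast

County-scale maize yield prediction with crop-model-coupled machine
learning, for agricultural-informatics researchers and forecasters who
want a transparent, testable alternative to black-box yield models.

## What it does

Process-based crop simulators encode physiology but are costly to run;
machine-learning models are cheap but opaque. `yieldcast` implements the
hybrid: simulator outputs (an APSIM-style block of 37 variables) join
weekly weather, layered soil, planting progress and historical yields as
features of five base learners, whose predictions are stacked by an
**optimized weighted ensemble** on the weight simplex:

```
minimize    sqrt( (1/n) Σ_i ( y_i − Σ_j w_j ŷ_ij )² )
subject to  Σ_j w_j = 1,   w_j ≥ 0,
            ensemble train MSE ≤ MSE of every base learner j
```

fitted on out-of-fold training predictions (SLSQP, multi-started, verified
against an exhaustive simplex-grid oracle). Evaluation is year-ahead
(train on 1984..t−1, predict t) with RMSE, relative RMSE (% of the
observed mean), mean bias error and R², aggregated by county, crop
reporting district and state, with storm-shocked counties excluded from
evaluation only, plus a Pearson analysis of county error against
soil-weather covariates.

Because the real data sources (NASS, SSURGO, mesonet reanalysis, gridded
simulator runs) cannot ship with a package, a first-class synthetic
generator reproduces their joint structure — yield trend (~0.12 Mg/ha/yr),
state→CRD→county hierarchy with cropland ratios, a crop-model block whose
`AnnualYield` correlates with true yield at a configurable fidelity
(default 0.82), pre-2000 planting-progress missingness in one state,
county-level simulator gaps, and an optional 27-county derecho-style
yield shock in 2020. See `vignettes/methods.Rmd` for the full stated
world and its limits.

## Worked example

```r
library(yieldcast)

cfg <- run_config(
  scenario = scenario_config(seed = 42),   # 72 counties, 1984-2020
  test_years = 2020, k = 60,
  tune = FALSE, oof_folds = 5,             # scaled-down demo budgets
  selection = list(ntree = 100, n_repeats = 3),
  seed = 42)
res <- run_experiment(cfg)

res$metrics[, .(model, n_obs, rmse, rrmse, mbe, r2)]
#>      model n_obs  rmse rrmse    mbe    r2
#> 1:  linear    45 0.493  4.72  0.049 0.851
#> 2:   lasso    45 0.487  4.66  0.021 0.854
#> 3:      rf    45 0.579  5.54 -0.203 0.794
#> 4:     gbA    45 0.601  5.76 -0.021 0.778
#> 5:     gbB    45 0.574  5.50  0.011 0.798
#> 6: ens_avg    45 0.521  4.99 -0.029 0.833
#> 7: ens_opt    45 0.488  4.68  0.020 0.854
```

45 test rows = 72 counties in 2020 minus the 27 shock-flagged counties,
which are excluded from evaluation (never from training). The optimized
ensemble matches the best base learner (here essentially the lasso) —
the dominance constraint guarantees it can never do worse on training
data, and here that carries to the test year. The fitted weights and the
top-ranked features are inspectable:

```r
res$per_year$year2020$weights_opt
#> <yc_weights> objective = 0.469541
#> linear  lasso     rf    gbA    gbB
#> 0.0000 0.9756 0.0000 0.0244 0.0000

head(res$per_year$year2020$ranking[, .(name, importance, rank)], 5)
#>             name importance  rank
#> 1:   yield_trend    1.35000     1
#> 2:   AnnualYield    0.16200     2
#> 3: AnnualBiomass    0.03680     3
#> 4:   soil_bd_d08    0.00965     4
#> 5:   soil_om_d02    0.00832     5
```

The county yield trend and the crop-model yield dominate the ranking, as
they should in a panel where both carry real signal. RMSE here is on
synthetic data (noise SD 0.5 Mg/ha) and says nothing about accuracy on
real panels; the pipeline's structure, not its headline number, is the
tested artifact.

A command-line interface mirrors the stages
(`simulate`, `preprocess`, `select`, `train`, `ensemble`, `evaluate`,
`analyze-errors`, `run-all`, `compare-apsim`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","yieldcast.R",package="yieldcast"))')" \
    simulate --out data
```

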