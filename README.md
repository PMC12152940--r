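# drqual

Quality-aware EC50 modeling from raw dose-response data.

In early-stage drug and pesticide design, dose-response experiments are
compressed into one number per molecule — the EC50 (IC50 for inhibition
assays) — before QSAR modeling. That compression throws away how well the
curve actually fitted: molecules measured few times, at high noise, or
active outside the tested concentration window carry EC50s that are close
to arbitrary, yet standard models weight them like every other point.
`drqual` keeps a per-molecule *fit-quality metric* next to each EC50 and
trains learners that use it.

## What it implements

**Analysis.** Responses (percent effect, clipped to [0, 100]) are fitted
with the two-parameter Hill equation

    Response(X) = 100 / (1 + 10^((LogEC50 - X) * HillSlope)),   X = log10(concentration)

by bounded least squares (`fit_hill_regression()`; slope fixed at 1 when
fewer than 3 distinct concentrations are available). The quality metric z
is the mean squared residual per measurement. Alternatively,
`analyze_bayesian()` evaluates a 100 x 10 posterior grid over
(LogEC50, HillSlope) under a Gaussian noise model with a pooled-variance
noise estimate, and uses the mean of 1000 posterior LogEC50 draws as the
target and their variance as z.

**Models.** The weight transform `p_i ∝ exp(-alpha * z_i)` feeds five
quality-aware learners, each collapsing to its quality-blind twin at
`alpha = 0` (bitwise, under a shared seed): random forest with parametric
bootstrap (`PB_RF`), weighted-split forest (`W_RF`), output-smearing and
variable-output-smearing forests (`OS_RF`, `VOS_RF`), and weighted
epsilon-SVR (`WSVR`) next to plain `RF` and `SVR`. Forests use 250 trees;
the tree engine and the per-sample-cost SMO solver are implemented in
C++ and validated against `rpart` and libsvm in the test suite.

**Protocol.** `random_search()` tunes each family by 20-draw random
search with 5-fold CV over the standard grids (max_features, fractional
min_samples_split, alpha, beta, epsilon). Crucially, models are *not*
scored by reproducing test-set EC50s: `evaluate_on_dose_response()`
predicts every held-out raw measurement through the slope-1 Hill curve at
the model's predicted LogEC50 and reports the RMSE over all
dose-response pairs, with a pairs-bootstrap SD and one-sided Wilcoxon
signed-rank comparisons at the 0.1% level.

**Synthetic assays.** `pubchem_like(n)` (shared 8-point grid, one
replicate, homoscedastic noise) and `basf_like(n)` (4-100 measurements
per molecule, per-molecule noise spanning 10x) generate datasets with
known ground truth for every test in the package.

## Worked example

```r
library(drqual)

ds <- basf_like(300, seed = 7)              # heteroscedastic synthetic assay
sp <- split_dataset(ds$sets, 0.5, seed = 7) # molecule-level split
qt <- analyze_regression(sp$train, ds$features[names(sp$train), ])
qt
#> <quality_table> 150 molecules, 256 features; target LogEC50 range [ -3.000, 3.000 ], mean quality 242.4

spec <- model_spec("W_RF", max_features = 0.33, min_samples_split = 0.01,
                   alpha = 0.33, seed = 7)
model <- fit_weighted_rf(qt, spec)
report <- evaluate_on_dose_response(model, sp$test, ds$features)
report
#> <evaluation_report> W_RF: RMSE = 28.6939 over 8032 dose-response pairs (150 molecules)
bootstrap_rmse_sd(report, seed = 7)
#> [1] 0.3057441
```

The RMSE is in response units (percent effect): on held-out raw
measurements this model's predictions are off by ~29 points on average —
most of it the assay's own noise floor (per-molecule sigma runs 5-50 in
this regime). The bootstrap SD says the RMSE itself is determined to
about +/-0.3.

A quality-blind baseline on the same split (`model_spec("RF", ...)`,
`fit_standard_rf()`) and `wilcoxon_compare(report_wrf, report_rf)` give
the paired comparison used throughout the package.

## Command line

A thin CLI over these functions ships in `inst/cli/drqual.R`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/drqual.R", package = "drqual"))')
Rscript $CLI simulate --preset basf_like --n 200 --seed 1 --out run/
Rscript $CLI analyze  --data run/dose_response.csv --features run/features.csv \
                      --mode regression --out run/table.csv
Rscript $CLI train    --table run/table.csv --family W_RF --seed 1 --out run/wrf.rds
Rscript $CLI evaluate --model run/wrf.rds --data run/dose_response.csv \
                      --features run/features.csv --out run/eval
Rscript $CLI compare  --report-a run/eval_pairs.csv --report-b other_pairs.csv \
                      --out run/compare.json
```

Every command writes its resolved options next to its outputs, so a run
is reproducible from its output directory.

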