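---
title: "Quality-aware EC50 modeling from raw dose-response data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-aware EC50 modeling from raw dose-response data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drqual)
```

## The problem

QSAR pipelines usually compress a molecule's raw dose-response
measurements into a single number — the EC50 (or IC50 for inhibition
assays) — and train a regression model on those numbers. Compression
discards how well the curve actually fitted the data. Molecules measured
few times, at high noise, or whose activity lies outside the tested
concentration window get EC50s that are little better than guesses, yet a
standard model treats them exactly like well-determined ones. `drqual`
implements the alternative: keep a per-molecule *fit-quality metric*
alongside the EC50 target and let the learner use it.

## Dose-response analysis

### The two-parameter Hill model

Responses are percent effect with asymptotes pinned at 0 and 100. With
$X = \log_{10}(\text{concentration})$, the efficacy curve is

$$\text{Response}(X) = \frac{100}{1 + 10^{(\mathrm{LogEC50} - X)\,\cdot\,\mathrm{HillSlope}}},$$

which is 50 exactly at $X = \mathrm{LogEC50}$ for every slope. Inhibition
data use the mirrored (decreasing) curve with the same midpoint, so both
assay directions run through identical machinery, selected by a
`direction` flag. The two-parameter form is adequate because responses
are normalized percent effect; recorded values outside $[0, 100]$ are
clipped to the asymptotes before any fitting (`clip_responses()`), making
every measurement representable by the model. We clip at *test* time too,
before computing RMSEs, for consistency — the protocol is then identical
on both sides of the split. All EC50 arithmetic is done on the log10
scale; the machine-learning target is LogEC50.

### Regression analysis

`fit_hill_regression()` minimizes the summed squared error over
(LogEC50, HillSlope). The optimizer is bounded: LogEC50 may range one
decade below the lowest and one decade above the highest tested
concentration, and HillSlope lies in $[0.1, 10]$ — the same ranges used
as priors by the Bayesian analysis, since sensible estimates outside them
are not identifiable from the tested window anyway. The fit starts at the
midpoint of the log-concentration range with slope 1 and, on optimizer
failure, restarts from a 5-point LogEC50 grid, keeping the lowest-SSE
result. (On 300 heteroscedastic molecules a 27-start multi-start search
reproduced the single-start estimates almost everywhere, so restarts are
kept as a fallback rather than a default.) With fewer than 3 distinct
concentrations there are not enough support points for two free
parameters; the slope is then fixed at 1 and only LogEC50 is optimized.

The quality metric is the mean squared residual per measurement,
$z_i = \mathrm{SSE}_i / n_i$. When replicates exist we divide by the total
measurement count, not the distinct-concentration count: $z$ is meant to
estimate the per-observation noise level around the curve, and the total
count is the natural denominator for that.

### Bayesian analysis

The alternative analysis assumes Gaussian measurement noise with a
variance estimated by pooling the unbiased within-group variances of all
(molecule, concentration) groups with replicates. A pooled estimate of
exactly zero is rejected (it would make the likelihood degenerate) and
routed to a configurable fallback variance, the same convention used when
no replicates exist at all. The posterior is evaluated on a discrete grid
of 100 LogEC50 values by 10 slope values with uniform priors over the same
ranges as the regression bounds. Two choices here were genuinely open:

* *Uniform in concentration or in log concentration?* We take the EC50
  prior uniform in $\log_{10}$ EC50. The stated prior range is
  multiplicative (0.1x the minimum to 10x the maximum tested
  concentration), which is natural on the log scale and matches the Hill
  parameterization; a uniform-in-concentration prior would put almost all
  its mass in the top decade.
* *Summarize EC50 or LogEC50 draws?* We summarize LogEC50, because the
  downstream model target is LogEC50 and a variance on the linear scale
  would be incomparable across potency ranges.

Likelihoods are accumulated in log space and normalized with the
max-subtraction trick, so molecules with hundreds of measurements cannot
underflow the grid. `posterior_summary()` draws 1000 cells with
replacement and reports the sample mean as the target and the sample
variance as the quality metric; the quality metric is *defined* as the
variance of a 1000-draw posterior sample, so sampling stays the default
and `exact = TRUE` (exact grid moments) is available for deterministic
checks.

## Quality-aware learners

All quality-aware models run through one weight transform
(`quality_weights()`):

$$p_i = \frac{e^{-\alpha z_i'}}{\sum_j e^{-\alpha z_j'}},$$

where $\alpha \ge 0$ controls how strongly quality is used and $z'$ is $z$
divided by its training-set mean. Mean-scaling is the default because raw
quality metrics differ by orders of magnitude between datasets (and
between the regression and Bayesian analyses), and a fixed $\alpha$ grid
must mean roughly the same thing everywhere; `scaling = "raw"` disables
it.

Seven families share two engines, so every $\alpha = 0$ model is
*bitwise identical* to its quality-blind twin under a shared seed — the
package tests assert this, and it guarantees hyperparameter search can
always fall back to ignoring quality:

* **RF** — baseline regression forest (uniform bootstrap, per-node random
  feature subsets, variance-reduction splits, 250 trees by default).
* **PB_RF** — parametric bootstrap: each tree's sample of $n$ points is
  drawn with probabilities $p_i$ instead of uniformly.
* **W_RF** — weighted forest: uniform bootstrap, but splits maximize the
  *weighted* variance reduction with weights $n p_i$ and leaves predict
  weighted means. The criterion is homogeneous in the weights, so only
  relative weights matter.
* **OS_RF** — output smearing: per-tree Gaussian noise with variance
  $\beta$ added to the targets replaces random feature selection (every
  split considers all features). The second argument of
  $N(0, \cdot)$ is read as a variance throughout.
* **VOS_RF** — variable output smearing: per-point noise variance
  $\beta\, e^{\alpha z_i'} / \overline{e^{\alpha z'}}$, whose mean over
  points is exactly $\beta$ and which reduces to OS_RF at $\alpha = 0$.
  An alternative rule sometimes written for this method, variance
  $\propto \beta p_i$, assigns *more* smearing to *better*-fit points,
  contradicting the method's stated intent that higher-quality points be
  smeared less; we default to the intent-honoring form and keep the
  literal rule behind `vos_literal = TRUE`.
* **SVR / WSVR** — $\varepsilon$-insensitive RBF support vector
  regression, solved by an SMO solver with per-sample box constraints.
  The kernel width is the common $1/(p \cdot \mathrm{Var}(X))$ default and
  the base cost is $C = 1$; WSVR scales each sample's cost to $C n p_i$.

The forest engine is implemented in C++ with a fast path for 0/1
features (fingerprint bits), and all of its randomness flows through R's
RNG, so `set.seed()` reproduces any fit exactly. The SMO solver is
validated against libsvm (via e1071) to ~1e-3 on shared problems, and a
single weighted tree is validated against `rpart`'s weighted anova tree
exactly.

## Model selection and evaluation

`random_search()` samples 20 hyperparameter combinations without
replacement from each family's grid (`search_space()` defaults:
max_features {0.1, 0.33, 0.5, 1.0}; min_samples_split {1%, 2.5%, 5%, 10%}
of the training size, converted to counts by round-half-up with floor 2;
$\alpha$ {0, 0.33, 1, 2}; $\beta$ {0.25, 1, 1.5, 2.5}; $\varepsilon$
{0.05, 0.1, 0.2, 0.5}) and scores each by k-fold cross-validated MSE on
the LogEC50 targets. Grids are small, so sampling without replacement
makes the 20 draws distinct and the search exhaustive whenever the grid
has at most 20 cells. We use 5 folds — a standard choice that keeps
per-fold training sets large at the dataset sizes involved.

Evaluation deliberately does **not** compare predicted EC50s with
test-set EC50s: a test molecule whose own curve fit is unreliable would
make that comparison meaningless. Instead, `evaluate_on_dose_response()`
predicts each held-out *measurement*: the model's predicted LogEC50 is
pushed through the Hill curve with slope fixed at 1 (the default slope;
slopes themselves are not modeled) at the measurement's log-concentration,
and the score is the RMSE over all available measurements. Splits are
always at the molecule level, and no EC50 is ever fitted on a test
molecule. Uncertainty on the RMSE comes from a pairs bootstrap (the
dose-response pair is the unit the RMSE is defined over, so it is the
resampling unit too, rather than the molecule). Model pairs are compared
with a one-sided Wilcoxon signed-rank test on per-measurement squared
errors at the 0.1% significance level, zero differences dropped, exact
null for 25 or fewer informative pairs and the normal approximation
above. One- versus two-sidedness and zero handling are conventions, not
prescriptions; they are configurable but these defaults match the
question actually asked ("is the quality-aware model better?").

## The synthetic assay generator

Because real PubChem and BASF datasets cannot ship with the package, the
generator (`generate_dataset()`, presets `pubchem_like()` and
`basf_like()`) creates dose-response data with known ground truth:
independent Bernoulli(0.1) feature bits, a sparse linear feature-to-
LogEC50 map (20 active features by default), true slopes log-uniform in
[0.5, 2] (realistic assay steepness concentrated around 1), and Gaussian
response noise, stored unclipped so the clipping rule is exercised
downstream. True LogEC50s are placed so that by default 80% fall inside
the tested concentration window and 20% outside — deliberately creating
the very-low/very-high-activity population whose curve fits are
unreliable. The shared grid spans log10 concentrations $[-2, 2]$ at 8
points, a typical 4-decade dilution series.

* `pubchem_like(n)`: every molecule measured once at the same 8-point
  grid, homoscedastic noise with sigma = 10 response units — the
  uniform-quality regime.
* `basf_like(n)`: per-molecule measurement counts uniform over 4..100
  (concentrations drawn from the grid with replacement) and per-molecule
  noise sigma log-uniform over [5, 50] — a 10x quality range; noisier
  overall, as reported for industrial pesticide assays.

What the generator does *not* emulate: correlated fingerprint structure
(real chemical libraries contain analog series, so real molecules have
close neighbors in fingerprint space; iid bits have none), plate effects
and outliers beyond Gaussian noise, and any dependence between a
molecule's noise level and its replicate count. These gaps matter for
interpreting the benchmark, as discussed next.

## What the standing benchmark does and does not show

The package's acceptance suite re-runs the whole pipeline on synthetic
data. The closed-form, recovery, equivalence, and statistical-exactness
checks are sharp: they validate the implementation against independent
oracles. The *headline-direction* benchmark — tuned W_RF and WSVR versus
their quality-blind twins on `basf_like` data over 10 seeds — is a
different kind of statement: it asks whether the heteroscedastic regime,
as specified, rewards quality information.

Two structural facts limit that reward here. First, the regression
quality metric $z_i$ estimates the per-measurement noise variance
$\sigma_i^2$, but a molecule's *target* error scales like
$\sigma_i/\sqrt{n_i}$; with measurement counts spread uniformly over
4..100 independently of $\sigma_i$, half of the target-error variation is
invisible to $z$ (the Bayesian posterior variance, which sees both
$\sigma_i$ and $n_i$, correlates better with realized target error in our
simulations: Spearman ~0.55 versus ~0.37). Second, with iid random
fingerprints the model error of a forest at 500 training molecules
(~0.65 log units) exceeds the average target noise (~0.36), so
downweighting data points costs more in effective sample size than it
recovers in target cleanliness, and the RBF SVR baseline — using the
conventional C = 1 and gamma = 1/(p Var X) defaults — degenerates toward
a near-constant predictor, leaving its weighted variant nothing to
improve. Both failure modes are well known for this family of methods
(quality weighting does not help when quality variation is
uninformative, and random search pays for an irrelevant extra search
dimension), while on real assay data with analog-series structure and
larger training sets the balance can tip the other way. The
benchmark is therefore reported honestly rather than engineered to pass:
where it fails under these study conditions, that is recorded as a
finding about the conditions, with the diagnostic evidence above.

## Numerical choices and edge cases

* Hill fits and posterior grids share the LogEC50 bounds
  [log10(0.1 min conc), log10(10 max conc)] per molecule.
* Pure nodes and nodes below `min_samples_split` become leaves; splits
  require a strictly positive weighted variance reduction with a
  relative tolerance of 1e-12, and ties go to the first candidate in the
  (random) feature order.
* `sigma2 = 0` from pooling is rejected and routed to the fallback.
* The SMO solver stops at a KKT violation below 1e-3 (matching libsvm's
  default) with an iteration cap that warns rather than errors.
* Degenerate posterior grids (all likelihoods underflowing) are
  impossible by construction: normalization happens in log space.
* All seeded helpers save and restore `.Random.seed`, so library calls
  never disturb a caller's RNG stream.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on synthetic data
at sizes chosen to exercise every code path at desk scale: 200 molecules
for fit-recovery checks, 300 for the equivalence suite, 1000 (500 train /
500 test) for the heteroscedastic benchmark, 2000 trees for the
bootstrap-frequency goodness-of-fit, and 5000 simulations for the
type-I-error check of the Wilcoxon comparison at the 0.1% level.
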