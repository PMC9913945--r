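---
title: "Classifying schizophrenia from cued Go/NoGo ERPs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying schizophrenia from cued Go/NoGo ERPs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`erpdx` implements a complete diagnostic-classification pipeline for
averaged event-related potentials (ERPs) recorded during a visual cued
Go/NoGo task, together with a synthetic cohort generator so every stage can
be exercised and tested without clinical recordings. This vignette explains
the scientific model behind each stage, the tunable parameters and their
defaults, the numerical conventions, and what the synthetic experiments do
and do not demonstrate.

## The classification problem

Subjects perform a cued Go/NoGo task: pairs of visual stimuli, where the
first stimulus (an animal image, "A") cues a possible response to the
second. Responding to A-A pairs is Go; withholding to A-P (plant) pairs is
NoGo; P-H pairs carry a novel sound. EEG is recorded from the 19 channels
of the 10-20 montage at 250 Hz, and stimulus-locked averages yield one ERP
waveform per (subject, condition, channel). The diagnostic task is binary
classification: schizophrenia patients (the positive class) versus healthy
controls, with a cohort of 132 controls and 68 patients as the reference
group sizes.

The pipeline restricts each condition to the channels and post-stimulus
interval where its ERP component is expressed:

| condition | component | channels | interval (ms) | reference stimulus |
|---|---|---|---|---|
| `plus1` | P3cue | T5, O1, O2, T6 | 320--520 | first |
| `plus2` | CNV | P3, Pz, P4 | 900--1080 | first |
| `nogo` | P300 NoGo | C3, Cz, C4, P3, Pz, P4 | 300--500 | second |
| `go` | P3b | C3, Cz, C4, P3, Pz, P4 | 250--450 | second |
| `ph` | P3a | C3, Cz, C4 | 160--220 | second |

This registry (`default_registry()`) is fixed; overrides are possible via
`registry_from_list()`. Milliseconds convert to sample indices with
round-half-to-even at the waveform's sampling rate, and intervals are
half-open `[start, end)`, so slice lengths are deterministic: 50, 45, 50,
50 and 15 samples at 250 Hz.

## Windowed feature extraction

Each sliced signal is cut into overlapping windows of `W` ms shifted by
`S` percent of the window size (`make_windows()`): the window length in
samples is `w = max(1, round(W * fs / 1000))` and the step
`s = max(1, round(w * S / 100))`. Both are floored at one sample so that a
5 ms window remains representable at 250 Hz (4 ms sample period). A
trailing remainder shorter than `w` is dropped; partial windows would make
per-window statistics incomparable.

Per window the extractor emits the minimum, maximum and mean; per signal
it adds the global mean, maximum and minimum and the serial number of the
first window attaining each global extremum (`argmaxwin`, `argminwin`,
ties resolved to the lowest window index). A signal with `n` windows thus
yields `3n + 5` features, named
`{condition}_{channel}_{type}_{window}` with the window number omitted for
global features -- `plus1_T6_min_1` is the minimum of the first window of
channel T6 in condition `plus1`. The extremum-window indices extend the
min/max/mean template with the `argmaxwin`/`argminwin` type tokens and are
scaled together with everything else.

The default per-condition window parameters (`default_window_params()`)
are `plus1` (49 ms, 50 %), `plus2` (5 ms, 50 %), `nogo` (49 ms, 100 %),
`go` (20 ms, 100 %) and `ph` (5 ms, 100 %), which at 250 Hz give
7/45/4/10/15 windows and 986 ERP features over the registry's 22
channel-signals. Four behavioral columns (`miss_pct`, `false_click_pct`,
`rt_ms`, `rt_var`) can be appended; they pass through the same scaler as
the ERP features, since the pipeline treats the concatenation as one
table.

## Behavioral summaries

A press is valid only within 200--1000 ms after the target stimulus.
Misses are Go (A-A) trials without a valid press; false clicks are NoGo
(A-P) trials with any press; reaction-time statistics cover valid Go
presses. `rt_var` is implemented as the coefficient of variation in
percent (`100 * sd / mean`): the study-scale magnitudes (8.4 healthy vs
12.0 patient, against mean RTs of 379/416 ms) are consistent with a
dispersion index of that form, not with a variance in ms².

Group comparisons use a classical one-way two-level ANOVA
(`anova_two_level()`), equivalently computable from group sizes, means and
SDs (`anova_from_summary()`). The published behavioral table's "±" values
are treated as standard deviations: plugging them into the
summary-statistic ANOVA reproduces the published F statistics (~56, ~9,
~48) to within a few percent, whereas reading them as standard errors does
not come close.

## Feature selection

Three strategies operate strictly inside training folds:

* **Random-probe Shapley filter** (`probe_shap_filter()`): one
  standard-normal probe column is appended, the model is fitted on the
  augmented table, and each feature's global importance is estimated as
  the mean absolute Shapley attribution over a training-row subsample.
  Features whose importance does not strictly exceed the probe's are
  dropped; the probe never survives. The idea: the probe is by
  construction irrelevant, so any feature that cannot beat it carries no
  usable signal.
* **Sequential feature selection** (`sequential_select()`): backward
  elimination starts from the full set and repeatedly removes the feature
  whose removal gives the highest inner-CV score, as long as the score
  does not drop; forward addition starts empty and adds features while
  the score strictly improves. Scoring uses stratified inner
  cross-validation (default 5 folds) with F1 as the default metric. Ties
  between candidate removals are broken by the smallest mean |Shapley|
  importance -- computed once on the full starting model with a small
  sampling budget, since it only orders ties -- then by name. An optional
  `max_steps` budget truncates the search; uncapped backward elimination
  is quadratic in the feature count and is only practical after a filter
  or on coarse feature tables.
* **Truncated SVD** (`svd_reduce()`): a rank-k principal-component
  projection fitted on training rows, with k the smallest count reaching
  the configured cumulative explained variance (default 0.95); held-out
  rows are projected with the training centering and rotation.

`probe_then_sfs` chains the probe filter with backward SFS on its
survivors.

## Shapley attribution

No Shapley library is available in this stack, so the package implements
two model-agnostic estimators (`shap_values()`) with the standard
background value function: the value of a coalition S at row x is the mean
model output over background rows with the S columns replaced by x's
values. The exact estimator enumerates all 2^d coalitions (practical to
d ≈ 12); the sampling estimator averages marginal contributions along
random feature permutations. Both satisfy additivity exactly (per-row
attributions sum to the prediction minus the mean background output; the
sampling estimator telescopes per permutation), and the exact estimator
satisfies the null-player and symmetry axioms exactly, which the test
suite verifies on linear models. The default background is a seeded
subsample of up to 100 training rows, and attributions are evaluated on
training rows, which is also what the interpretation module reports.

## Models

* **Logistic regression** with L1 or L2 penalty via coordinate descent
  (`glmnet`), with the inverse-strength convention `lambda = 1/(C * n)`.
* **k-nearest neighbours** with unweighted neighbour votes, so
  probabilities are multiples of 1/k (default k = 11).
* **SVM** with RBF kernel (libsvm via `e1071`); `gamma_mode = "scale"`
  sets gamma to `1 / (n_features * var(features))`, and the default cost
  is C = 1/3. Probabilities come from a Platt sigmoid calibration of the
  decision values fitted on the training data only -- libsvm's built-in
  probability machinery uses an internal random inner CV that cannot be
  seeded from R, and bit-reproducibility under a fixed seed is a package
  contract.
* **Stacking**: one logistic regression per feature group (the five
  conditions, plus the behavioral columns when enabled), with an SVM
  meta-model trained on the base probabilities. Meta-features are
  out-of-fold probabilities from a seeded stratified inner CV, which
  avoids the optimism that in-sample base probabilities would leak into
  the meta-model.

Class imbalance (132 vs 68) is handled by inverse-frequency class weights
(`class_weight`, `weighted_loss`) or seeded minority upsampling
(`upsample`); the two give cross-validated F1 within a few points of each
other on the default synthetic cohort, matching the reported equivalence
of these remedies. kNN uses unweighted votes by construction, so its
imbalance remedy is upsampling.

Scalers (`standard`, `minmax`, `robust`, `none`) are fitted on training
rows only; zero-spread columns get scale 1 so constant features pass
through rather than producing NaNs.

## Evaluation protocol

`cross_validate()` runs stratified k-fold cross-validation (default 10
folds, seeded shuffle). Within each fold, scaler, selection and model see
training rows only. The decision threshold is chosen where sensitivity
and specificity are closest -- the candidate grid is the midpoints of
sorted unique probabilities, minimizing |TPR - TNR| with ties broken by
larger TPR + TNR, then smaller threshold. Because the protocol does not
specify which data the threshold may see, the package chooses it on
out-of-fold predictions from an inner 5-fold split of the training side,
never on the held-out fold, to avoid optimistic bias. Per-fold
sensitivity, specificity, F1 and rank-statistic AUC (ties get half
credit) are reported as mean ± SD, and per-fold test confusion counts are
summed into a single matrix whose totals must equal the cohort
composition.

`grid_search()` evaluates any list of fully explicit grid points (window
parameters × selection × model × scaler) and ranks by mean F1, with mean
AUC and then the smaller retained-feature count as tie-breaks; failing
points are recorded and skipped.

## The synthetic cohort generator

The generator (`simulate_cohort()`) is a waveform model, not a
physiological simulation. Each condition's component is a Gaussian bump
in time centered at the midpoint of the condition's analysis interval,
multiplied by a per-channel topography weight and a per-subject amplitude
drawn from the group distribution, plus i.i.d. Gaussian noise on the
averaged trace (`noise_sd_uv`, default 1.5 µV). The CNV (`plus2`)
component is negative; all others positive. Patient amplitudes are
attenuated relative to healthy, as reported for the P300 family and CNV
in schizophrenia. Because no per-wave amplitudes are published, the
defaults are calibration choices fixed once: healthy/patient peak
amplitudes of 8/5 (P3cue), 6/4 (CNV), 9/6 (P300 NoGo), 8/5.5 (P3b) and
7/4.5 µV (P3a), with between-subject SD at 25 % of the group mean. These
produce per-component effect sizes around d ≈ 1--1.6 -- strong but not
degenerate, so the recovery experiment is informative without being
trivial.

Behavioral summaries are drawn from group-wise normal models whose
defaults are the study-scale statistics (healthy misses 1.6 ± 2.8 %,
false clicks 0.7 ± 1.3 %, RT 379 ± 79 ms, RT variability 8.4 ± 2.6;
patients 9.4 ± 11.4, 2.0 ± 6.7, 416 ± 92, 12.0 ± 4.8), with rates clipped
to [0, 100] % and RTs to the 200--1000 ms validity window.
`simulate_trials()` emits trial-level responses consistent with a
subject's summary, closing the loop with the behavioral module.

`effect_scale` multiplies the healthy-patient gap in **both** the
component amplitudes and the behavioral parameters: at 0 patients are
drawn from the healthy distributions everywhere, making a true null
cohort -- the natural definition here, since the pipeline consumes ERP and
behavioral features together and a "null" cohort with a live behavioral
gap would not be null for the classifier.

Randomness flows through one seed with per-subject derived streams, so a
cohort is bit-reproducible and individual subjects do not change when the
group sizes do.

What the generator does *not* emulate: single-trial variability and
trial-count effects on the averages, channel covariance from volume
conduction, latency jitter between subjects, artifacts, medication
effects, or any realistic ERP morphology beyond one Gaussian bump per
condition. Passing the recovery experiment therefore shows that the
pipeline's plumbing -- extraction, selection, training, thresholding,
aggregation -- recovers a known group difference without leakage; it says
nothing about clinical accuracy on real EEG, and the published clinical
metrics are out of the package's reproduction surface for exactly that
reason (the clinical data are not shared).

## Null behavior of cross-validation

With `effect_scale = 0` the mean cross-validated AUC over five seeded
cohorts lies within [0.4, 0.6], which the acceptance suite checks.
Individual null cohorts tend to land slightly above 0.5: each subject's
features are driven by a handful of latent amplitude draws, and a finite
cohort of 200 subjects will show small chance group differences in those
latents that a classifier can pick up within the cohort even though they
do not generalize beyond it. This is a property of cross-validation on
finite cohorts with low-dimensional latent structure, not of leakage; the
same pipeline on i.i.d. noise features centers at 0.5, and the dedicated
leakage test verifies that held-out rows never influence training-fold
fits, scaler statistics, selected features or thresholds.

## Numerical conventions and degenerate inputs

* ms-to-sample conversion uses R's round-half-to-even; intervals are
  half-open.
* Window length and step floor at one sample; a window longer than the
  signal is an error naming the condition.
* Extremum-window ties resolve to the first window; if a global extremum
  falls in dropped remainder samples, the index falls back to the best
  windowed value.
* Amplitudes are written to CSV with six decimals, so write-then-load is
  the identity on the written values.
* Constant columns: scalers pass them through with scale 1;
  `direction_summary()` reports correlation 0 with a degenerate flag.
* Threshold candidates are midpoints of unique probabilities; a
  single-valued probability vector uses that value itself.
* Zero pooled within-group variance makes the ANOVA undefined and is an
  error.

## Problem sizes used by the test and acceptance runs

The worked runs use the study-scale cohort (132/68, 10 outer folds). The
recovery configuration (`smoke_grid_point()`) uses one-window-per-signal
window parameters (180 features with behavior), backward SFS on 3 inner
folds with a 2-step budget, and the RBF SVM with C = 1/3 -- a single grid
point sized so the complete nested procedure (including the quadratic
backward pass) runs in minutes while exercising every stage. Unit tests
use cohorts of 14--70 subjects and toy tables of up to ~20 features;
estimator-convergence checks use up to 200 sampling permutations; the
extractor is checked against a brute-force reference on 1,000 random
signals, and the balanced-threshold rule against an exhaustive scan on
100 random instances.

## Known limitations

* Backward SFS from the full 986-feature table is computationally
  quadratic and only practical behind the probe filter or a step budget.
* The probe filter's null behavior (dropping nearly everything on pure
  noise) depends on a sparse or well-regularized model; with a dense
  model, roughly half of the noise features tie-break past the probe by
  chance.
* kNN ignores class weights; only upsampling rebalances it.
* The registry covers five conditions totalling 22 channel-signals; the
  narrative count of "18 signals in four conditions" from the source
  study's introduction is inconsistent with its own methods table, and
  the registry follows the methods table.
* The stacking meta-model consumes only 5--6 meta-features; with small
  cohorts its inner CV can be noisy, and it is provided for architectural
  completeness rather than as the best performer.
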