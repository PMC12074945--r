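---
title: "Methods: the fittnet prescription model"
author: "fittnet authors"
output: rmarkdown::html_vignette
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`fittnet` builds individualized aerobic exercise prescriptions for older
adults: given age, sex, BMI, baseline VO₂max and a target relative
improvement in cardiorespiratory fitness, it predicts the four FITT
elements (frequency in days/week, intensity in %HRR, session time in
minutes, programme volume in weeks). This vignette is the package's own
account of the model, its numerical choices, and what its tests do and do
not establish.

# The coding layer

The network never sees raw prescriptions. Quantities are coded
deterministically and invertibly:

* **Intensity** is mapped from %HRR to `(pct − 50)/100`, i.e. the decimal
  value minus 0.5, so that 50 %HRR — the midpoint of common aerobic
  training ranges — is the coding origin and 60 %HRR codes to 0.1. Studies
  reporting an intensity *range* are coded by the range midpoint. The map
  is affine and order-preserving, so coded errors translate directly to
  %HRR errors (×100).
* **Age, BMI and baseline VO₂max** carry one decimal; **improvement,
  session time and volume** carry two. All rounding is round-half-up
  (ties away from zero), applied once at encoding; base R's round-to-even
  would make printed 1- and 2-decimal conventions irreproducible.
* **Sex** is one-hot as a single 0/1 code (0 = female). **Improvement** is
  stored as a fraction (0.10 = 10 %); the roster reader accepts percents
  and divides by 100. **Frequency** has no transform: it is carried as raw
  days/week and rounded to the nearest positive integer only when a model
  output is decoded. Nothing in the published coding dialect assigns it
  one, and an affine map of an already small integer would change nothing.

Decoding attaches a symmetric intensity range (±5 %HRR by default, ±10 on
request) around the predicted midpoint, reflecting how intensity targets
are operationalized in supervised sessions.

By default the coding layer is the *only* input scaling. An optional
min–max switch (`attach_input_scaling()`) maps each input feature to
[−1, 1] using training-set ranges, and the mapping travels with the
network so inference uses the same ranges. We recommend switching it on
whenever tanh hidden layers are used with raw physiological units: ages
near 70 or session times near 50 put fan-in-scaled preactivations deep in
tanh saturation, where Jacobians vanish and training stalls; MATLAB-style
training pipelines apply the same mapping silently via `mapminmax`. The
package default stays "off" so that the coding dialect alone defines the
model's inputs; the heavier examples and tests enable it explicitly.

# The corpus: Gaussian augmentation of study summaries

Training data are subject-level, but the underlying evidence is
study-level: each literature row gives group size, age/BMI/VO₂max as
mean ± SD, sex composition, the observed relative VO₂max improvement, and
the study's prescription. `augment_study()` simulates each study's
subjects: age, BMI and baseline VO₂max are drawn independently from
Normal(mean, SD) — one 1×3 record per subject — while sex is assigned by a
Bernoulli draw with the study's male proportion and the improvement and
prescription target are held fixed at the study's values. The corpus size
equals the summed subject counts exactly.

Numerical choices:

* **Truncation.** Gaussian draws can produce impossible values (a negative
  BMI); such draws are rejected and redrawn. At the scales of real study
  tables (e.g. BMI 24.6 ± 3.4) the rejection probability is below 10⁻¹²,
  so moments are unbiased for practical purposes. Zero SDs are legal and
  degenerate to the mean.
* **Streams.** Every study draws from its own child stream keyed by study
  id (`child_seed()`), so permuting table rows permutes provenance blocks
  without changing any study's draws, and stages of the pipeline can be
  reproduced independently from one root seed.

The default generator scale — 68 studies totalling 1,594 subjects, age
means 60–80 y (SD 2–7), BMI means 21–30 (SD 1–4), baseline VO₂max means
10–35 mL·kg⁻¹·min⁻¹ (SD 1–5), improvements 5–20 %, prescriptions of
2–5 d/wk at 50–80 %HRR, 20–60 min over 8–24 weeks, 10–40 subjects per
study — reflects the composition of the aerobic-training literature in
older adults that this class of model is built from.

What the synthetic tables do **not** emulate: correlations between
covariates within a study (real cohorts with higher BMI tend to have lower
baseline VO₂max), between-study heterogeneity in how intensity scales were
harmonized (%HRR vs %HRmax vs %VO₂max), publication bias, and measurement
error in the summary statistics themselves. Passing tests on this
generator therefore demonstrate that the pipeline is correct and that the
trainer recovers learnable structure — not that a model trained on any
particular literature table is clinically valid.

For recovery tests the package also generates labelled response surfaces
(`synth_response_surface()`): a fixed smooth map in which coded intensity
decreases in BMI and age and session time increases with the improvement
target ("smooth" mode), or a randomly initialized network of the model's
own architecture ("teacher" mode, a realizable target). The generating
function is returned with the data so tests can measure recovery directly.

# The network and its trainer

The regressor is a 5–12–10–8–4 multilayer perceptron. Output units are
linear (the standard regression head); hidden units are tanh. The hidden
activation is a package choice — any sigmoidal unit would serve — exposed
via `init_network(activation = )`, with `"identity"` available to make the
whole network linear for closed-form cross-checks. Widths follow the
classical empirical sizing rule `n₁ = round(√(n_in + n_out)) + a` with
a ∈ [1, 10], giving candidates 4–13 for the 5-input 4-output model
(`hidden_neuron_range()`, with the `a_range` argument as the override);
the 12–10–8 stack sits in that band.

Weights are initialized symmetric-uniform with fan-in scaling
(±0.7·√(3/fan-in), a Nguyen–Widrow-like range), biases zero, from a seeded
draw. One **epoch** is one accepted (or retry-exhausted) full-batch
update.

**The Levenberg–Marquardt update.** With residuals
`e[(i−1)m + o] = ŷ(xᵢ)ₒ − yᵢₒ` (sample-major) and Jacobian `J = ∂e/∂w`, the
step solves the damped, regularized normal equations

```
(JᵀJ/nm + αD + λI) Δw = Jᵀe/nm + αDw
```

and proposes `w − Δw`, where `D` is the identity on weights and zero on
biases. This is the exact Gauss–Newton treatment of the loss
`L = MSE + α Σ wⱼ²`: the MSE normalization (1/nm, pooled over samples and
outputs) and the penalty live inside the linear algebra, so accepted steps
minimize the same L the loss function reports. Biases are excluded from
the penalty by default (penalizing output offsets shrinks predictions
toward zero for no benefit) and switchable via `penalize_bias`.

**Damping schedule.** λ starts at 0.01; accepted steps multiply it by 0.1
(floor 10⁻¹²), rejected ones by 10 (ceiling 10¹²). A candidate is
accepted iff it does not increase the regularized loss, so the accepted
loss sequence is non-increasing by construction. A singular system at
small λ is treated as a rejection — the damping increase regularizes the
solve — never as an error. If λ reaches its ceiling without acceptance
the trainer reports a plateau and stops.

**Jacobians.** The analytic mode runs one reverse accumulation per output
dimension, vectorized over samples; the finite-difference mode perturbs
each parameter by Δ = 10⁻⁵ (forward differences). The two agree to ≤10⁻⁴
relative error on random full-size networks (a standing test), and the
finite-difference error shrinks linearly in Δ, as expected for a smooth
activation.

**Stopping.** Training stops at the epoch cap (default 1,000), when the
training MSE reaches the error-precision goal (default 10⁻⁷), or when the
validation loss has not improved for `patience` epochs (default 10); the
returned model is the best-validation snapshot. Divergence (non-finite
loss) aborts with a diagnostic rather than returning garbage.

**η and β.** The learning rate (0.01) and momentum factor (0.9) have no
role in a pure LM update; they drive only the plain
gradient-descent-with-momentum trainer (`method = "gd"`), retained as the
traditional back-propagation baseline LM is contrasted against. The grid
search still enumerates them so that the full 3×3×3 candidate set
{0.001, 0.01, 0.1} × {0.5, 0.7, 0.9} × {0, 0.001, 0.01} is explored
regardless of method.

# Model selection

`published_split_sizes()` states the printed 80/10/10 floor-division
convention (1,594 → 1,275/159/159 — note the floors drop one sample).
The operational splitter `make_splits()` never drops data: a seeded
shuffle followed by contiguous segmentation into 10 balanced segments
(sizes differ by ≤1, remainders in the earliest segments, which the role
assignment gives to training as 8 train / 1 validation / 1 test).

`grid_search()` trains every configuration on each inner train/validation
split and minimizes mean inner-validation RMSE. One weight initialization
is drawn per inner round and shared across configurations, so comparisons
differ only in the hyperparameters. Exact ties — guaranteed under LM for
rows differing only in η or β — resolve to the smaller α, then the smaller
η, by pre-ordering the grid; reproducibility is the only stake in the
choice.

`nested_cv()` wraps this in the outer loop: for each of the 10 outer
folds, weights are reinitialized from a fresh child seed, the grid search
runs entirely inside the outer-training portion (the held-out fold cannot
reach the inner loop — asserted structurally on every run), the winner is
retrained with full epoch caps using one inner segment for early stopping,
and the held-out fold is predicted. Inner-loop training uses a reduced
epoch cap (a quarter of the base cap by default, configurable) to keep the
search tractable. Per-round RMSE/MAE/R² are computed on the encoded
4-dimensional outputs jointly — all residuals pooled — matching the
one-number-per-round presentation of cross-validation tables; the "Best"
row is the minimum-RMSE round, reported column-consistently from that
round. Note that pooled metrics are dominated by the outputs with the
largest physical ranges (minutes and weeks); per-element error ratios
(below) are the complementary, scale-free view.

# Validation statistics

Conventions, fixed once and used everywhere:

* SDs use the n−1 denominator.
* Band membership (error-ratio tolerance, hit-rate bands, Bland–Altman
  limits) is inclusive at the boundary.
* Printed rates are rounded half-up to whole percents (43/61 → 70 %);
  dropout rates to one decimal.
* Error ratios are `100·(predicted − target)/target` per element
  (intensity, time, volume), so a negative mean is under-prescription;
  pairs with a zero target element are excluded with a warning. The
  default tolerance band is ±20 %.
* Hit rates report the fraction of observed improvements inside
  mean ± k·SD, k = 1 or 1.96; adding a constant to all improvements moves
  the band with the mean and leaves the rate unchanged.
* Bland–Altman differences default to expected − observed (switchable);
  bias, limits of agreement bias ± 1.96·SD, and the percent of points
  within the limits are reported. For large Gaussian difference samples
  the coverage of the sample's own limits is ≈95 % by construction — a
  standing statistical test at n = 10⁴.
* Expected-versus-observed regression is ordinary least squares
  (`stats::lm`) with the slope's 95 % CI and non-zero-slope p-value.

RMSE² = MSE and MAE ≤ RMSE hold on any common residual set; a published
table violating them signals differing units or definitions, not a
property this implementation can reproduce.

# Prescription and screening

`prescribe()` encodes the profile with the requested target improvement
(default 0.10 — the literature-typical 12-week CRF gain in older adults),
forward-passes, and decodes. Frequency is rounded to the nearest positive
integer; intensity gets its ±5 %HRR band. Decoded elements are screened
against broad plausibility bounds — intensity 40–90 %HRR, time 10–90 min,
volume 4–52 weeks, deliberately wider than guideline ranges (50–85 %HRR,
30–60 min) to avoid false alarms — and violations are **flagged, never
clipped or blocked**: a silent clip would hide a badly trained model. A
non-positive time or volume output yields no prescription and a flag.
`batch_prescribe()` maps this over a roster, reports per-row failures in a
flags column (never fatally), and summarizes each element as mean ± SD
(min–max).

# Problem sizes in the test suite

The suite exercises the full 5–12–10–8–4 architecture but at corpus sizes
chosen for a single-CPU run: 300-sample teacher surfaces for recovery and
nested cross-validation (with a 2-configuration grid, 2 inner rounds, and
25/80-epoch inner/final caps), 80–200-sample surfaces for trainer
properties, 10⁴ draws for statistical checks, and 4-study/80-subject
corpora for the pipeline round-trips. These sizes are large enough that
the asserted properties (Jacobian agreement, monotone accepted loss,
closed-form equivalences, R² > 0.99 on realizable targets, ≈95 % coverage)
are far from their thresholds, and small enough to keep the suite fast.
Corpus-scale conservation is additionally asserted at the full 68-study /
1,594-subject default.

# Known limitations

* The model prescribes from five inputs; exercise type, comorbidities,
  medication and adherence are outside its scope, as is computing %HRR
  from measured heart rates or converting between intensity scales.
* Augmentation treats covariates as independent Gaussians within a study;
  real subject-level joint distributions are richer.
* Pooled encoded-scale metrics mix units; compare models on the
  per-element error ratios as well.
* LM is full-batch: memory grows with samples × parameters (the Jacobian),
  which is fine at the thousands-of-samples scale this model targets and
  wrong for much larger corpora.
* The screening bounds warn, never block; clinical use requires human
  review of flagged prescriptions.
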