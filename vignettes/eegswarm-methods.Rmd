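---
title: "Multi-domain EEG features and swarm-based feature selection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-domain EEG features and swarm-based feature selection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegswarm)
```

## The problem

Automatic seizure detection classifies short windows of EEG into healthy,
interictal (between seizures), and ictal (during a seizure) states. Two
practical obstacles dominate: raw time-domain samples are poor inputs for
conventional classifiers, and rich feature sets extracted from several
signal domains are highly redundant, which inflates training cost and can
hurt generalisation. `eegswarm` implements a complete pipeline that
addresses both: a 35-dimensional multi-domain feature summary per window,
followed by a two-stage selector that first searches for feature subsets
with high classification value and then strips out mutually correlated
survivors.

## Preprocessing

Records are bandpass filtered with a fourth-order Butterworth at
0.5–70 Hz and notch filtered at 50 Hz (quality factor 30, a narrow notch
standard for mains removal). Both filters are applied forward–backward,
so the pipeline is zero-phase: wavelet and spectral features downstream
are not distorted by filter delay. For sampling rates whose Nyquist
frequency falls at or below 70 Hz the upper band edge is clamped to
`0.99 * fs / 2`; the Bonn-style rate of 173.61 Hz needs no clamping.

Filtered records are cut into windows of 1,024 samples whose consecutive
windows share 64 samples (stride 960). We read the conventional "overlap
of 64" figure literally as shared samples; a stride-64 reading is also
supported via the `stride` argument of `pipeline_config()`, since
published segment counts for the classical datasets cannot be
reconstructed from any single uniform stride on 4,097-sample records and
the choice is therefore genuinely open. Segments are split into
train/validation/test partitions stratified by class (the classical
protocol is 90/5/5); stratification is our choice — it keeps rare-class
counts stable in the small validation and test fractions — with floor
allocation and remainders assigned to train, then validation, then test.

## The 35 features

Each window is decomposed to five levels with a decimated discrete
wavelet transform (default `db4`, the Daubechies filter most common in
epilepsy EEG work; `haar` and `db2` are available). The six coefficient
sets D1–D5 and A5 cover halving frequency bands; at 173.61 Hz they align
approximately with gamma, beta, alpha, theta, delta, and sub-delta. The
transform is periodized and orthonormal — the test suite checks energy
conservation — and is implemented directly in the package as the dyadic
low/high-pass cascade.

Five statistics summarise each coefficient set:

* **LSWT** — log-sum `sum(ln |c_j|)`;
* **MEAN** — mean absolute value;
* **ABS** — mean power `mean(c_j^2)`;
* **STD** — `sqrt(mean((c_j - mean(|c_j|))^2))`. Note the centring on
  the *absolute* mean: this is the field-reported variant and is the
  package default. It differs from the conventional standard deviation
  on sign-alternating input (for `(1, -1, 1, -1)` it gives `sqrt(2)`,
  not 1); `stat_std(..., center = "conventional")` provides the usual
  form;
* **RAT** — ratio of absolute sums of adjacent sets,
  `sum(|c_i|) / sum(|c_{i+1}|)`. Six sets give only five adjacent
  pairs; to complete the widely quoted count of 30 time-frequency
  features the sixth ratio closes cyclically (A5 against D1). A strict
  `adjacent5` mode (34 features total) is available through
  `extraction_config(rat_mode = "adjacent5")`. A literal reading of the
  printed ratio formula (same sub-band, shifted index) is degenerate —
  it is ≈1 for every input — so the package follows the accompanying
  text ("adjacent subbands") instead.

The remaining five features are Welch log band powers. The Welch
estimator windows the segment (Hamming taper, `M = 256`, 50% overlap —
all configurable; none of these constants is fixed by the published
pipeline description), normalises each periodogram by the window power
`U = mean(w^2)` and the density factor `fs * M`, and averages. The
one-sided density integrates to the signal variance (tested against a
direct-DFT oracle and a Parseval check). Band power is the natural log
of summed density over half-open bands `[low, high)` — delta 0.1–4,
theta 4–8, alpha 8–12, beta 12–30, gamma 30–70 Hz — so contiguous bands
never double-count a bin; the gamma edge is capped below Nyquist.

Logs use the natural base throughout (the base is not fixed by the
published formulas). All logs and ratio denominators are clamped at
`1e-12`, so an all-zero window produces finite, well-defined features
(LSWT at the clamp floor, MEAN/ABS/STD zero, RAT exactly 1, band powers
`ln 1e-12`).

## The two-stage selector

**Stage 1 — modified binary particle swarm.** Each particle holds a
real-valued position per feature; a stochastic sigmoid transfer maps
positions to 0/1 masks (the transfer rule is not fixed in the published
description; the sigmoid rule is the standard binary-PSO convention, and
an all-zero mask is repaired by one redraw and then a forced single
selection). Fitness of a mask is the stratified 3-fold cross-validated
accuracy of a seeded random forest on the selected columns, computed on
the training partition only. Personal and global bests update when a
candidate improves accuracy, or ties it (within `1e-12`) with a strictly
smaller subset — the size tie-break is what drives the selector toward
compact subsets.

The velocity update is

```
v' = w v + phi * (c1 r1 (pbest - x) + c2 r2 (gbest - x))
```

with the Clerc–Kennedy constriction factor
`phi = 2 / |2 - c - sqrt(c^2 - 4 c)|`, `c = c1 + c2`. The printed form
of this factor in the source literature is typographically garbled; the
closed form implemented here is the standard one consistent with its
stated purpose (bounding the dynamics when `c > 4`). With the default
`c1 = c2 = 2.05`, `phi ≈ 0.7298`; when `c <= 4` the factor is inactive
(1, with a warning). The inertia weight `w`, which appears in the
velocity rule but is given no value in the source description, decays
linearly from 0.9 to 0.4 over the run. Velocities are clamped at
`±v_max = 4`. Defaults are 30 particles and 50 iterations with a
15-iteration stall stop; everything is configurable and seeded, and runs
are bit-reproducible.

**Importance and retention.** After the run, feature `j` receives weight
proportional to its fitness-weighted frequency among all recorded
personal-best masks, normalised to a maximum of 1. This aggregation rule
is a package convention — the published account reports importance
weights without defining their computation. The `top_k = 10` highest
weights (ties broken by canonical feature order) proceed to stage 2.

**Stage 2 — Pearson redundancy filter.** Scanning the retained list in
rank order, a feature is kept iff its absolute Pearson correlation with
every already-kept feature is at most `delta = 0.6`; the top-ranked
feature is always kept, zero-variance columns are dropped with a
warning, and every examined pair is recorded. The published worked
example of this filter is internally inconsistent (it removes its
top-ranked feature yet keeps a pair whose printed correlation exceeds
the threshold), so no removal order can reproduce it exactly; the greedy
keep-first rule implemented here is declared as the package's rule and
validated on synthetic tables with planted correlation instead.

## Classification and evaluation

Four classifier configurations are provided: an SVM with a fifth-degree
polynomial kernel (`gamma = 0.1`, `cost = 1`), a single-hidden-layer
neural network with 19 units and softmax/cross-entropy output, a seeded
random forest, and gradient-boosted trees. Features are standardised
(fit on training rows only) for the SVM and the network; tree models
consume raw features — scaling is not part of the published protocol and
is applied only where the model family requires it.

Evaluation uses one-vs-rest sensitivity, specificity and accuracy per
class, in percent. Two F1 variants are computed and kept strictly apart:
`F1_paper = 2*AC*SE/(AC+SE)`, the harmonic mean of accuracy and
sensitivity exactly as the source formulas print it, and
`F1_conventional`, the usual precision/recall harmonic mean. The two are
asserted unequal on an asymmetric confusion matrix in the test suite so
one can never silently stand in for the other. Multiclass summaries are
reported both macro-averaged (unweighted over classes) and pooled-micro,
since the published headline rows do not say which reduction they use.
The standard protocol is stratified 10-fold cross-validation with a
pooled confusion matrix; 95% confidence intervals are Student-t over the
fold accuracies (the interval method is unspecified in the source; the
t interval over 10 folds is our convention), clipped to [0, 100].

## The synthetic-data generator

`gen_eeg_record()` emulates exactly the property the pipeline exploits:
class identity carried by band-power composition and transient
spike-wave content. A record is a sum of band-limited noise components
(white noise filtered into each clinical band by the same tested
Butterworth code, scaled to a per-band standard deviation), biphasic
3 Hz spike-wave transients at Poisson times, and white noise. The
default recipes — alpha-dominant healthy background; a flatter
interictal background with sporadic spikes (0.5/s); a high-amplitude
delta-dominant ictal rhythm with frequent spikes (3/s) — were chosen
once so that the full 35-feature profile separates the classes with a
comfortable margin while no single feature is sufficient, making
selection non-trivial but end-to-end tests stable. What the generator
does *not* model: 1/f spectral slope, non-stationarity within a record,
eye-blink/muscle artifacts, multi-channel spatial structure. Passing
tests on synthetic data therefore demonstrate the pipeline's mechanics
and its statistical behaviour under known ground truth, not clinical
performance.

`gen_feature_table()` generates labelled tables with known informative
columns (class means separated by `effect_size` within-class SDs),
planted `rho`-correlated duplicate columns, and pure noise — the ground
truth needed to assert selection recovery. One caveat that shaped the
test design: two informative features are themselves correlated through
the class structure (for three balanced classes,
`r = (2e^2/3) / (1 + 2e^2/3)` at effect size `e`), so recovery
experiments use `e = 1.0` (`r ≈ 0.4`), keeping informative pairs clearly
below the `delta = 0.6` filter threshold; at `e = 1.5` informative pairs
sit at the threshold itself and the filter's behaviour on them is a coin
flip. When a feature and its *exact* duplicate are planted, the two are
indistinguishable to any selector, so recovery is counted per planted
group (either member), never per original column.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on synthetic data
at desk scale, chosen as the smallest sizes at which the stochastic
properties are stable: swarm-vs-exhaustive comparison on 8 features
(255 subsets, 120 samples, 10 swarm seeds), selection recovery on 12
features (240 samples, 10 seeds), ablation on 35 features (240 samples,
10 seeds, 30 particles x 40 iterations), and an end-to-end run with 100
records per class (1,200 windows). Fitness evaluations are memoised per
mask within a swarm run. The published headline accuracies for the Bonn
and CHB-MIT datasets are not reproduction targets: they depend on the
original downloads and on pipeline constants (exact segment counts,
wavelet family, swarm hyper-parameters) that the source does not fix.
The `reproduce-bonn` CLI subcommand will run the full pipeline on a
user-supplied local copy of the Bonn dataset, best-effort, and never
fetches data.

## Known limitations

* The EDF reader covers continuous fixed-rate 16-bit recordings (the
  CHB-MIT layout); EDF+ annotations and discontinuous files are out of
  scope — seizure intervals come from a sidecar TSV.
* The DWT uses periodic boundary handling; features near window edges
  differ slightly from implementations using symmetric extension.
* Importance aggregation and the redundancy-filter order are declared
  conventions (see above), not reconstructions of the source's unstated
  rules; results that depend on them (e.g. exactly which of two highly
  correlated features survives) should be interpreted accordingly.
* The ANN configuration trains by quasi-Newton optimisation without
  early stopping; the validation partition is reserved but only the
  final test evaluation consumes it by joining it to the training set.
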