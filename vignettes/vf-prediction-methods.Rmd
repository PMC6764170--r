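---
title: "Predicting ventricular fibrillation from HRV and QRS shape: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting ventricular fibrillation from HRV and QRS shape: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(vfforecast)
```

## The problem and the analysis windows

Ventricular fibrillation (VF) is a lethal arrhythmia; an implantable
defibrillator that could anticipate onset even half a minute ahead would gain
valuable preparation time. `vfforecast` implements a complete
prediction-from-ECG analysis built around two windows defined relative to the
VF onset time: a 120-s *analysis* ("required") window ending 30 s before
onset, from which all features are computed, and the final 30 s
(*forecast* window), which is deliberately never touched — the classifier must
commit before it. Control subjects contribute a 120-s window from the start
of their recording (the choice of control offset is a configuration option;
nothing in the method depends on it, and the default of 0 s is deterministic).

Windows are half-open `[start, end)` over 0-based sample times: a beat
exactly at the end boundary belongs to the next window, one exactly at the
start is kept. This avoids double-counting without any special cases.
Records whose onset arrives sooner than 150 s after the start cannot supply
the full analysis window and are excluded, with the record id carried in the
error — the same rule a curated arrhythmia database applies when recordings
are shorter than the required length.

## Feature families

### HRV features (11)

All heart-rate-variability features are computed from the RR tachogram (beat
annotation times differenced into ms intervals). Conventions, chosen once:

* **Mean NN, SDNN** — mean and *population* (1/N) standard deviation of the
  intervals. All dispersion statistics in the package use the population
  form for internal consistency.
* **RMSSD** — root mean square over the N−1 successive differences.
* **pNN50** — percentage of successive differences whose magnitude exceeds
  50 ms. The denominator is the number of *intervals* N, following the
  feature's printed definition; the more common N−1 convention is available
  via `pnn50_denominator = "differences"`. On typical 120-s windows the two
  differ by under 1%.
* **VLF, LF, HF, LF/HF** — band powers of the tachogram spectrum over
  (0, 0.04], (0.04, 0.15] and (0.15, 0.4] Hz, in ms². The tachogram is
  cubic-spline resampled at 4 Hz (the conventional rate: a 256-point Welch
  segment then spans 64 s, so a 120-s window yields three 50%-overlapped
  Hann segments), linearly detrended, and passed through Welch's averaged
  periodogram (256-point Hann, 50% overlap). Detrending removes the DC
  component, so the VLF band is effectively open at 0. When HF power is
  exactly zero the LF/HF ratio is reported as `NA` with a warning rather
  than infinity.
* **SD1, SD2, SD1/SD2** — Poincaré-plot dispersions:
  `SD1² = Var(RRᵢ − RRᵢ₊₁)/2` (population variance), and SD2 from the
  identity `SD2² = 2·SDNN² − SD1²`. The identity is exact under these
  population conventions and is enforced by tests to 10⁻⁹ relative. A
  radicand driven fractionally negative by floating error (pure alternation
  is the worst case) is clamped to zero with a warning; SD1/SD2 is `NA`
  when SD2 is zero.

### QRS shape features (4)

The QRS complex is delineated per beat between the PQ junction and the
J point. The boundary search scans outward from the R peak (from 16 ms up to
120 ms) for the nearest sample where the smoothed slope magnitude falls
below 5% of its local maximum *and* the signal sits within 12% of the R
amplitude from the local quiescent level; if a side finds no such point the
fixed ±60 ms fallback is used. These constants bracket normal QRS durations
and are exposed as arguments. The per-beat baseline is the mean of the
40-ms PR segment ending at the PQ junction — a local rather than global
baseline, so slow drift does not bias the area.

From each windowed beat:

* **signed area** — the (uniformly weighted) sum of baseline-corrected
  samples between the boundaries, in µV·samples; the sign is preserved, so
  net-downward complexes are negative. The weighting kernel is a
  configuration hook; uniform weights are the default and the simplest
  defensible reading of an amplitude-modulation ("ECG-derived respiration"
  style) area statistic.
* **R amplitude** — the maximum baseline-corrected sample in the window.

The four record-level features are `QRSaM`/`QRSaSD` (mean and population SD
of the *absolute* areas — polarity must not matter for the area statistic)
and `RPampM`/`RPampSD` (mean and population SD of the amplitudes, signed).

Beat positions come from annotations when present (annotations are
authoritative, as in cardiologist-annotated databases); otherwise a
Pan-Tompkins-style detector (5–15 Hz band-pass, derivative, squaring,
150-ms moving average, adaptive threshold, 200-ms refractory period)
supplies them, with each detection refined to the local raw-signal extremum.

## Classification

The primary classifier is a fully connected network with one hidden layer
of six rectified-linear units and a single sigmoid output read as P(VF):

$$ p(\mathbf{x}) = \sigma\!\big(\mathbf{w}_2^\top\,
   \mathrm{relu}(W_1 \mathbf{x} + \mathbf{b}_1) + b_2 \big). $$

Biases enter before the activations, the standard formulation that keeps
the output a probability; a strict variant that adds biases after each
activation (with the output clipped to [0, 1]) is available behind
`bias_after_activation = TRUE` for fidelity to an alternative reading of
the layer equations, but is not the default precisely because the
post-activation output bias breaks the probability interpretation.

Training minimises binary cross-entropy with Adam (β₁ = 0.9, β₂ = 0.999,
ε = 10⁻⁸). Hyperparameters not dictated by the architecture are fixed at
conventional values for a dataset of ~50 rows: learning rate 0.001,
200 epochs, mini-batches of 8, seeded small-uniform initialisation
(U(−0.5, 0.5)/√fan-in). The gradients are hand-coded and verified against
central finite differences to 10⁻⁵ relative in the test suite; training is
bit-reproducible under a fixed seed.

Features are z-scored (`z = (x − μ)/s`, population s) before any
classifier sees them. Inside cross-validation the scaler is fit on the
nine training folds only, so no test-fold statistics leak into training;
a `scaler_scope = "global"` mode reproduces the simpler all-data scaling
some analyses use.

Four comparison classifiers run through the same interface with library
implementations and their defaults, recorded in the run manifest:
radial-kernel SVM and Gaussian naive Bayes (e1071), k-nearest neighbours
(k = 5, class), and random forest (randomForest, seeded).

## Evaluation

Cross-validation is stratified 10-fold, repeated 10 times with fresh fold
assignments per repeat. Class remainders are dealt to the currently
smallest folds, which with 27 + 28 samples provably yields fold sizes of
5 and 6 while keeping both classes in every fold. Per fold, sensitivity,
specificity and accuracy are computed with VF as the positive class
(decision threshold 0.5, ties to VF); per repeat, the held-out scores are
pooled into a single ROC, integrated trapezoidally. The trapezoidal AUC
with tie-collapsed thresholds equals the rank-based (Mann–Whitney)
statistic exactly, and the suite asserts that equivalence to 10⁻¹² on
random score sets.

Group differences per feature use Welch's unequal-variance two-tailed
t-test by default — group SDs of these features differ by orders of
magnitude, which is exactly the regime where pooled-variance testing is
anti-conservative; the pooled variant is an option. Identically constant
groups resolve to t = 0, p = 1 by convention. Algorithm accuracies are
compared with a balanced one-way ANOVA followed by Tukey HSD, with both
degrees of freedom reported.

## The synthetic cohort generator

Because the underlying arrhythmia recordings cannot be bundled, the
package ships a generator that emulates the statistical structure the
analysis relies on, with complete ground truth:

* **RR model** — `RR(t) = mean_rr + a_LF sin(2π f_LF t) + a_HF sin(2π f_HF t) + ε`,
  ε white Gaussian, evaluated at the cumulatively built beat times. The
  modulation frequencies are constrained to the LF and HF bands, so
  spectral features have a known home; a 200-ms refractory floor keeps
  intervals physical under extreme noise draws.
* **ECG model** — a sum-of-Gaussians P–QRS–T template per beat (plus
  triangular and rectangular QRS variants with closed-form areas for
  tests). Per beat, the R amplitude follows
  `r_amp_base (1 + depth · sin(2π f_LF t))` and the QRS width is scaled by
  a lognormal-free Gaussian jitter `(1 + N(0, area_jitter_sd²))`; white
  sample noise is added last. The truth attribute carries each beat's
  analytic amplitude and discrete noise-free signed area. A full
  dynamical-system ECG model would add realism the pipeline never
  consumes — only the QRS window statistics and the RR series matter here.
* **Cohorts** — a master seed fans out to per-record child seeds, so a
  cohort is bit-reproducible while records stay independent. VF records
  place their onset uniformly in [150 s, 170 s] (any placement admitting
  the full analysis window is equivalent for feature extraction) and are
  cut 2 s after onset; controls are 125 s long. Per record, lognormal
  multipliers scale the RR modulation/noise amplitudes
  (`rr_scale_sdlog`), the QRS amplitude/jitter parameters
  (`qrs_scale_sdlog`) and the mean RR (`rr_mean_sdlog`). This
  between-record heterogeneity is what makes the groups *distributions*
  rather than point masses: without it every record in a group would carry
  essentially identical features and any classifier would be trivially
  perfect.

### Preset calibration

The `"calibrated"` preset fixes the two groups' parameters so that the
VF group exceeds controls in SDNN, RMSSD, pNN50, SD1, SD2, QRS-area SD
and R-amplitude mean/SD — the direction pattern reported between VF-prone
and control subjects — while mean NN stays statistically indistinguishable.
The heterogeneity scales are chosen so the HRV features overlap moderately
between groups (network accuracy typically high-80s to low-90s %) and the
QRS shape features separate widely (typically 98–100%), reproducing the
qualitative headline that QRS shape predicts the pre-VF state better than
conventional HRV. The `"separable"` preset shrinks heterogeneity so both
families separate cleanly; `"null"` gives both groups the control
parameters, for false-positive and permutation checks. These values were
fixed once during development and are not tuned per analysis.

What passing tests on this generator do **not** show: robustness to real
morphologies (notched QRS, bundle-branch block, ectopy — there is no
ectopic-beat filtering because annotations are trusted verbatim), to
non-stationary noise and electrode artifacts, or to the actual
physiological mechanism of pre-VF morphological change, which remains
speculative; the generator's amplitude/area modulation is a statistical
stand-in, not a mechanistic claim.

## Problem sizes and numerical choices

The repeated-cohort structural check in the test suite uses 50 seeded
cohorts of 27 + 28 records with 2×10-fold cross-validation per feature
set; the acceptance script and the package defaults use the full 10×10
schedule on a single cohort. The type-I-error check uses 1000 two-group
comparisons of SDNN from null-preset RR series (8 per group). Tolerances:
formula oracles at 10⁻⁹ relative, AUC equivalence at 10⁻¹², gradient
check at 10⁻⁵ relative, analytic-area checks at 2%.

Degenerate inputs are resolved explicitly rather than left to float
semantics: constant series give zero dispersions (and `NA` ratios with
warnings), zero-variance features abort standardization with the feature
named, single-class training data is refused, and beats whose QRS window
would cross a record edge are skipped with a log message.

## Known limitations

* The synthetic generator, not real recordings, backs all shipped
  verification; quantitative accuracies on clinical data will differ.
* Only VF-onset prediction is modelled; ventricular tachycardia is out of
  scope.
* The QRS boundary search is tuned for adult sinus-rhythm morphology at
  128–500 Hz sampling; very wide or fragmented complexes will fall back to
  fixed offsets more often.
* Feature concatenation (HRV + QRS, 15 inputs) is supported as plumbing
  but carries no calibrated expectation.
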