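---
title: "Preictal-state classification from scalp EEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preictal-state classification from scalp EEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Epileptic seizures are preceded, in many patients, by minutes of subtly
altered cortical dynamics — the *preictal* state. An epoch-level classifier
that can tell a 10 s window of preictal EEG from ordinary interictal
(*baseline*) EEG is the core of a seizure early-warning system. `preictal`
implements such a classifier as a modular pipeline:

1. **Preprocessing** — mains notch filters (50/60 Hz) and an optional 35 Hz
   low-pass, all zero-phase.
2. **Epoching** — 10 s windows, labeled preictal (1) when they fall in the
   configured window before an annotated seizure onset, baseline (0) when far
   from every seizure, balanced per subject.
3. **Features** — per epoch, a 5-band STFT amplitude profile
   (delta/theta/alpha/beta/gamma × time steps) and a Pearson channel-correlation
   map, each divided element-wise by the subject's average baseline profile.
4. **Embedding** — the two normalized matrices are rendered into a two-block
   image and passed through a pluggable convolutional backbone, giving a
   fixed-length feature vector per epoch.
5. **Classification** — six RBF SVMs trained on stratified leave-one-fold-out
   bags; their binary outputs are averaged and rounded (ties toward
   preictal) into the final decision.
6. **Evaluation** — per-subject 60/20/20 train/validation/test splits,
   accuracy / sensitivity / precision / F1 (reported as mean ± sd across
   subjects, plus pooled), ROC/AUC from mean continuous member scores, and
   ablation arms (backbone swap, single SVM, no vote, 20 s epochs).

## Model and conventions

**Bands.** delta 0.5–4, theta 4–8, alpha 8–12, beta 13–30, gamma 30–80 Hz.
Bin-to-band assignment is half-open `[low, high)`; the 12–13 Hz gap between
alpha and beta follows the band table itself.

**STFT.** 1 s Hann window, 50% overlap — 19 frames per 10 s epoch at 256 Hz.
One second resolves the 0.5 Hz delta edge acceptably while leaving enough
frames for a time axis; both are conventional choices for scalp EEG. Band
amplitude is the *mean magnitude* over the band's bins (not power), averaged
over channels, calibrated so a unit sinusoid at a bin centre reads 1.

**Correlation maps.** Plain Pearson `r` between all channel pairs over the
epoch's samples. A zero-variance channel has no defined correlation; its
off-diagonal entries are set to 0 and flagged in a QC attribute rather than
propagating `NA`.

**Baseline normalization.** For each subject the element-wise mean of the
band profiles and correlation maps over baseline epochs is the divisor for
every epoch's features. Inside `run_experiment()` the averages use *training*
baseline epochs only, so no test-epoch statistics leak into the
normalization. Cells whose baseline mean is below `1e-8` in magnitude are
mapped to ratio 1 ("no change") and counted, which keeps the division total.
Correlation ratios may leave `[-1, 1]` or flip sign when a baseline entry is
small or negative; values pass through unchanged, since the normalization is
defined as plain division.

**Gamma versus the low-pass.** A 35 Hz low-pass would structurally zero the
30–80 Hz row, so band features are computed from the notch-filtered signal,
and the low-pass stage is applied only when the gamma band is disabled
(`use_gamma = FALSE`).

**Image composition.** There is no canonical way to turn two feature
matrices into a backbone image, so the package uses the simplest
deterministic layout: band profile bilinearly resampled into the top half,
correlation map into the bottom half, min–max scaled to `[0, 1]`, replicated
over 3 channels. A perfectly baseline-like (constant) layout has no dynamic
range and maps to an all-zero image by a guard. Bilinear resampling uses
aligned corners, so resizing to the native size is the identity — that
property is load-bearing for the permutation contract tests.

**Backbones.** The registry decouples the pipeline from any particular
network. The built-in `tinycnn` is a deterministic random-weight CNN (four
3×3 stride-2 convolutions, 3→16→32→64→128 channels, He-scaled weights from
a fixed private seed) whose read-out concatenates the global mean and
standard deviation of every channel at every stage (480 values). Pooling all
stages, not only the last, was a measured design decision: with frozen
random weights, a last-stage-only average pool discarded class information
that is plainly present in the image (held-out accuracy 0.88 versus 1.00 for
raw pixels on a pilot synthetic set), while the multi-scale read-out
retained it (0.98). A pretrained network of the EfficientNet family can be
registered through `register_backbone()` when its exported forward pass is
available; nothing in the pipeline depends on which backbone is plugged in.

**SVM ensemble.** Members are RBF SVMs with `C = 1`, tolerance `0.001`, and
`gamma = "scale"` = `1 / (n_features × var(x))`. The members are trained with
`scale = FALSE` so that the gamma rule applies to the feature space it is
defined on; silently standardizing columns first would change every kernel
width. Member diversity is bagged stratified leave-one-fold-out (six folds;
member *k* sees all folds but *k*); random 80% feature subspaces are
available as an alternative (`diversity = "features"`). The vote averages
the six *binary* outputs and rounds half-up, so a 3–3 tie predicts preictal
— the tie-break deliberately favours sensitivity, the costlier error
direction in seizure warning. Continuous decision values are used only for
ROC analysis, oriented toward the preictal class.

**Splitting.** Stratified by label within subject. The default `"blocked"`
method assigns temporally contiguous chunks to train/validation/test
(seeded chunk-role permutation), limiting leakage between adjacent 10 s
epochs, which share slow EEG structure. A plain stratified random split is
available (`method = "random"`) for fidelity to protocols that ignore this.

**Metrics.** Accuracy, sensitivity, precision and F1 evaluate their defining
count ratios exactly and are reported in percent; a zero denominator yields
an explicit "undefined" marker, never a silent 0. AUC comes from the
standard threshold sweep (equivalently the scaled Mann–Whitney U), computed
by pROC and cross-checked in the tests against a brute-force pairwise
oracle.

## The synthetic-EEG generator

Real scalp-EEG archives cannot ship with a package, so every stage is
testable against a generator with *known* structure. Each latent state
(baseline, preictal) specifies per-band carrier amplitudes and a target
inter-channel correlation matrix. Per state segment, each band is realized
as band-limited Gaussian noise (white noise through an order-4 Butterworth
band-pass; band-limited noise rather than pure tones keeps STFT estimates
non-degenerate and correlation maps full-rank), mixed across channels by the
Cholesky-type square root of the correlation target, scaled by the band
amplitude, summed, and topped with white sensor noise. Fixed seeds make
realisations bit-identical, and the generator restores the caller's RNG
state.

Default baseline amplitudes (delta 4, theta 2, alpha 2, beta 1, gamma 0.5;
arbitrary µV-scale units) give the familiar roughly 1/f spectral fall-off of
scalp EEG. The stock two-state cohort (`synthetic_cohort_specs()`) uses 8
subjects × 21 channels × 256 Hz × 66 min, two seizures per subject (onsets
at 50 and 65 min, 40 s duration), a 10 min preictal window (120 preictal
epochs per subject), and a 30 min baseline guard, which leaves exactly 120
baseline epochs — classes balance deterministically at 240 epochs per
subject. These sizes were chosen once as a realistic desk-scale cohort and
are stated here as the package's own study conditions. The preictal effect
in the `"strong"` scenario doubles the alpha amplitude and raises the
exchangeable channel correlation from 0.20 to 0.45; the `"null"` scenario
makes both states identical, so any classifier should sit at chance.

What the generator does *not* emulate: seizure morphology, artifacts
(EMG/EOG), non-stationary drifts, electrode pops, inter-subject variability
of spectra. Passing the synthetic end-to-end checks therefore demonstrates
that the pipeline's machinery recovers a known band-power/correlation
signature at realistic SNR — not that it attains any particular accuracy on
clinical recordings.

A note on an oracle-derived constant: doubling the alpha carrier doubles the
alpha-band *component*, but the measured alpha-profile ratio between states
converges to ≈1.86, not 2.0, under the default band mixture — neighbouring
bands leak into the 8–12 Hz bins and dilute the ratio. The tests assert the
oracle value; with an alpha-only configuration (no leakage sources) the
ratio is 2.0 within Monte-Carlo error.

## Numerical and degenerate-input choices

* Zero-phase filtering is forward–backward application (squared magnitude,
  zero group delay); the "non-causal FIR" of the preprocessing stage is
  realized as a windowed-sinc linear-phase FIR of order 50 applied
  forward–backward. Notches are biquad band-stops with quality factor 30.
* A preictal window extending before the recording start is truncated with a
  warning; epochs never overlap a seizure interval; a recording shorter than
  one epoch yields an empty set with a warning.
* If fewer baseline epochs are eligible than preictal epochs exist, all are
  kept and the imbalance is warned about rather than silently discarding
  preictal data.
* EDF I/O quantizes to the container's 16 bits against each channel's
  physical range; round-trips are exact to one quantization step.
* `vote()` rejects non-binary member outputs; `svm_ensemble()` refuses
  single-class data and fewer than `n_members` samples per class.

## Problem sizes and runtime

The test suite and the acceptance script run the full pipeline on the stock
8-subject cohorts described above (roughly 240 epochs × 8 subjects per
scenario, 21 channels at 256 Hz), which takes a few minutes per cohort on a
single desktop core; the unit tests use smaller recordings (2–6 channels,
minutes long). Segmentation arithmetic is verified on annotation-driven
dummy recordings at a reduced sampling rate, since epoch counting depends
only on interval arithmetic, not on signal content.

## Known limitations

* Accuracies on clinical recordings cannot be established here: they require
  a full scalp-EEG archive and, for the intended transfer-learning backbone,
  pretrained ImageNet weights. The package validates the machinery,
  interfaces and invariants on synthetic data with known structure, and
  accepts real EDF data when the user supplies it.
* The channel list of real 10–20 recordings varies between files; the reader
  takes an explicit, ordered `channel_selection` and resolves duplicate
  labels to the first occurrence.
* Correlation-map normalization by division is faithful to its definition
  but statistically awkward near zero baseline correlations; the QC
  attributes expose guard counts so users can audit affected cells.
* The number of baseline profiles used per subject is `n_profiles_used` in
  the baseline object; requesting more than exist (e.g. 1000 from 540)
  honours availability with a warning rather than failing.
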