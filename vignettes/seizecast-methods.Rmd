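---
title: "Methods: seizure prediction with autoencoder transfer learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seizure prediction with autoencoder transfer learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Patient-specific seizure prediction classifies short windows of scalp EEG as
*interictal* (baseline) or *preictal* (approaching a seizure), then turns the
window-level outputs into clinically meaningful alarms. Seizures are rare, so
each patient contributes few preictal examples — too few to train a deep
network from scratch reliably. `seizecast` implements the transfer-learning
remedy: a deep convolutional autoencoder (DCAE) is pretrained, unsupervised,
on a large *source* EEG corpus; its encoder is then frozen and reused as a
feature extractor inside each patient's predictor, so the patient-specific
fit only has to learn a small recurrent head.

Because clinical EEG corpora are private, the package ships a synthetic EEG
generator that reproduces the *structural* properties the pipeline relies
on, making every stage testable end to end.

## Prediction horizon: SOP and SPH

Two intervals define a correct alarm:

* **SPH** (seizure prediction horizon, default 10 min): the minimum warning
  time. An alarm closer than the SPH to the onset is useless and counts as
  false.
* **SOP** (seizure occurrence period, default 30 min): the interval after
  the SPH in which the predicted seizure must occur.

An alarm at time $t$ is therefore *true* iff some onset falls in
$[t + \mathrm{SPH},\; t + \mathrm{SPH} + \mathrm{SOP}]$. The *preictal*
period is the union, SOP + SPH = 40 min before onset. Windows are labelled
by their start time (intervals half-open): preictal in
$[\mathrm{onset} - 2400\,\mathrm{s}, \mathrm{onset})$, excluded if they
overlap the 30 min after onset (ictal/postictal), interictal otherwise.

Training uses only the 4 h before each training seizure: 3 h 20 min as
interictal, the 30-min SOP span as preictal; the SPH windows are dropped
(at inference time nothing is dropped). Only *leading* seizures — onsets at
least 4.5 h apart, onset-to-onset, since onset is the only clinician-marked
time — anchor training and evaluation, so every preictal span is
uncontaminated by a preceding seizure.

## Models

**DCAE.** The encoder stacks six `Conv1D → BatchNorm → swish →
SpatialDropout` blocks (swish $x\,\sigma(x)$; spatial dropout removes whole
feature maps). Default filters (32, 32, 64, 64, 128, 128), kernel 5, stride
2 per layer: a 10-s, 2560-sample window compresses to a 40-step feature
sequence. The decoder alternates three ×4 nearest-neighbour upsamplings with
three convolutions (4³ = 2⁶ restores the length exactly; the build refuses
configurations whose stride and upsampling products disagree). The final
convolution is linear because it reconstructs standardized, unbounded
signals. Layer hyperparameters are package defaults chosen to satisfy the
stated layer counts and exact shape restoration; all are configurable.

**Predictor.** The encoder's 40-step output feeds a bidirectional LSTM
(64 units per direction by default) *within* a single window; the
concatenated final states of both directions pass through one dense layer
with a two-way softmax. The recurrence is deliberately intra-window:
firing-power postprocessing assumes one independent output per 10-s window,
so cross-window recurrence would blur that granularity.

**Transfer vs standard.** In *transfer* mode the encoder weights are copied
from a pretrained DCAE bundle (a configuration-hash check forbids silent
partial loads) and frozen — bit-identical before and after any fit, with
BatchNorm running statistics and no dropout, i.e. the whole encoder acts as
a fixed deterministic feature extractor. In *standard* mode everything
trains from random initialisation. Standardization follows the training
statistics: the source corpus' per-channel mean/sd in transfer mode, the
patient's own training windows in standard mode.

The networks are implemented natively in R (im2col + GEMM convolutions,
backpropagation through time for the BiLSTM, Adam), so the package has no
deep-learning runtime dependency; gradients are verified against finite
differences in the test suite.

## Optimisation protocol

DCAE: mean squared reconstruction error, batch 2048, up to 2000 epochs,
early stopping with patience 200 on a random 80/20 holdout. Predictors:
binary cross-entropy, balanced batches of 64 (each batch: 32 majority-class
windows, 32 minority windows oversampled with replacement; one epoch is one
pass over the majority class), up to 500 epochs, patience 50, five repeats
with distinct recorded seeds; per-patient metrics average the repeats. Both
use Adam at learning rate 3e-4. Early stopping restores the
best-validation-loss weights (restore-best strictly dominates last-epoch
and is the standard reading). The 80/20 predictor holdout is random by
window and label-stratified, with the seed recorded in the split plan.

## Firing power and alarms

Classifier outputs $o[k] \in [0,1]$ (the softmax preictal probability — the
threshold-0.5 majority reading coincides with hard decisions, but the
probability retains information) arrive on a nominal 10-s grid. The firing
power is the trailing moving average over $\tau$ = SOP/10 s = 180 slots:

$$ fp[n] = \frac{1}{\tau} \sum_{k=n-\tau+1}^{n} o[k], $$

with gap slots (artifact-rejected or missing windows) contributing $o = 0$
while still occupying calendar time, so a sustained gap of $\tau$ slots
drives $fp$ exactly to 0. The window is normalised over $\tau$ samples so
that $fp \in [0,1]$ with $fp = 1$ for a saturated window.

An alarm fires on an upward crossing of the threshold (default 0.5) and
starts a 40-min (SOP + SPH) refractory period. Crossings during warm-up
(the first $\tau$ slots of a segment, where the average is computed over
zero-padded history) or refractory are consumed: after the refractory
period a *fresh* crossing is required, so a sustained plateau cannot
re-alarm indefinitely. This crossing semantics is the conservative reading
of "alarm as soon as a majority appears".

## Evaluation

* **Seizure sensitivity (SS)** = predicted test seizures / test seizures.
* **FPR/h** = false alarms / (interictal hours − false alarms × 2/3 h):
  false alarms per interictal hour after removing the refractory time the
  false alarms themselves consume. Interictal time counts only valid
  recorded time inside test segments, minus preictal spans — consistent
  with the gap-aware firing power.
* **Surrogate validation**: with the alarms held fixed, each test-seizure
  onset is redrawn uniformly within its test segment (at least SOP + SPH
  after the segment start), SS is recomputed against the same alarms, and
  the observed SS is compared with 30 surrogate SS values by the one-tailed
  Monte-Carlo rank p-value $(1 + \#\{SS_{surr} \ge SS_{obs}\})/31$. The
  rank form is exactly valid under exchangeability of observed and
  surrogate seizure times; a t-based prediction interval was measured at
  type-I error 0.083 on 600 simulated null patients (SS is discrete, the
  normal approximation is poor at 30 surrogates) versus 0.033 for the rank
  form, which the test suite re-verifies against the nominal 0.05. The
  procedure is a pure function of alarms and segments.
* **Approach comparison**: per-patient means (over the 5 repeats) of SS and
  FPR/h are compared between standard and transfer modes with one-tailed
  Wilcoxon signed-rank tests (transfer SS greater; transfer FPR/h lower),
  $\alpha = 0.05$.

Seizures are split chronologically, first 60% (ceiling) for training; each
test seizure's segment runs from 30 min after the previous onset to its own
onset. Splits are checked for temporal leakage: no training window may lie
in a test segment.

## The synthetic generator

The background of each channel is the sum of four band-limited Gaussian
processes — delta (0.5–4 Hz), theta (4–8), alpha (8–13), beta (13–30) —
with standard deviations proportional to the inverse band-centre frequency
(a 1/f-weighted, EEG-like spectrum; total 20 µV by default) at 256 Hz, 19
channels. Artifacts are sparse 400-µV, 0.5–1-s transients at a configurable
hourly rate; they are *not* pre-marked — the preprocessing stage must catch
them by amplitude thresholding, and the generator's ground-truth intervals
verify it does. Gaps are carried as a per-sample validity mask.

The preictal signature multiplies the alpha-band component by
$1 + s\,r(t)$, with $r$ ramping linearly from 0 to 1 over the 40 min before
each onset and $s$ the effect size. At $s = 2$ a plain alpha-band-power
threshold separates preictal from interictal windows with AUC ≈ 0.95, so
$s \ge 1$ is a safe "learnable" regime; at $s = 0$ the labels are
statistically invisible (the suite checks p-value uniformity across seeds).
Real preictal EEG has no agreed statistical description; the ramp is a
simulation choice that makes the learning experiment winnable, not a claim
about real dynamics — passing tests demonstrate the pipeline's mechanics,
not clinical performance. Ictal morphology and postictal dynamics are not
modelled (both are excluded from training and evaluation anyway).

Generation is bit-deterministic given the spec's seed (R's default
Mersenne-Twister). Datasets round-trip through 16-bit EDF plus an
annotation CSV (`patient_id,onset_s,offset_s`); the EDF reader/writer is
built into the package.

## Preprocessing

Recordings are polyphase-resampled to 256 Hz (a package-own windowed-sinc
implementation, gain-exact to ≈0.04% in the passband), band-pass filtered
0.5–100 Hz with a 50-Hz notch (zero-phase Butterworth cascade with
odd-reflection end padding so edge transients decay outside the data), and
amplitude-thresholded (default 300 µV, ±0.25 s padding) into the validity
mask; samples are never altered by rejection. A published artifact-removal
network exists for this task, but the downstream pipeline only requires a
validity mask, so a configurable threshold rule is used instead. Windows
are non-overlapping 10-s segments; a window is valid iff 100% of its
samples are valid (configurable) — the conservative default propagates gaps
honestly to the alarm layer. Filtering idempotence holds to < 1% in signal
*power* (a second pass removes only transition-band residue; an
amplitude-RMS reading of that tolerance is unattainable for any realisable
filter). The per-channel sd used for standardization is floored at 1e-6 µV
so flat channels cannot blow up the division.

## Desk-scale profile and problem sizes

`desk_profile()` runs the whole experiment on one workstation CPU in a few
minutes: 4 channels, encoder filters (4, 4, 8, 8, 16, 16), BiLSTM 8 units,
one synthetic patient with four leading seizures on a compressed timeline
(minimum lead gap 1.2 h instead of 4.5 h; ≈8.4 h of recording), 12–15
epochs, and learning rate 3e-3. The raised rate is deliberate: 3e-4 is
calibrated for corpora with thousands of optimiser steps per epoch, whereas
a desk-scale epoch is ~30 steps, so the step budget — not the protocol — is
scaled. Full-protocol values (19 channels, batch 2048/64, 2000/500 epochs,
patience 200/50, lr 3e-4, 5 repeats) remain the package defaults. The test
suite and `scripts/acceptance.R` use the desk profile; with a
signature strength of 2 the transfer pipeline reliably attains SS > 0 on
the held-out seizure with finite FPR/h.

## Numerical choices and degenerate inputs

* Resampling ratios are matched by continued fractions (denominators up to
  10⁴); irrational ratios beyond 1e-9 are rejected.
* The firing-power warm-up (first τ slots) computes the average over the
  zero-padded history but suppresses alarms — conservative.
* FPR/h is rejected (with a diagnostic) when false-alarm refractory time
  exhausts the interictal denominator; the pipeline records such repeats as
  `NA` rather than aborting the experiment.
* Surrogate segments shorter than SOP + SPH cannot host a surrogate onset
  and are dropped with a warning.
* All-zero paired differences give p = 1 (with a warning) in the Wilcoxon
  comparison.
* Recordings shorter than one window segment to an empty `window_set`;
  empty prediction series produce empty firing-power series and no alarms.
* Weight bundles serialise byte-stably (version-2 R serialisation, XDR).

## Known limitations

* The generator's stationary band-limited background lacks real EEG's
  nonstationarity, inter-channel correlation structure, and artifact
  diversity; results on it say nothing about clinical performance.
* The BiLSTM sees one window at a time; multi-window recurrence is out of
  scope.
* With a single test seizure per patient (the desk profile), surrogate
  validation rarely certifies above-chance performance — one seizure cannot
  beat the 0.05 level unless fewer than 1/20 surrogates score, which is
  statistically honest but means `above_chance` is mostly informative with
  several test seizures.
* The native R networks are CPU-bound and desk-scale; they are faithful,
  not fast.
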