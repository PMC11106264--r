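---
title: "Methods: sleep staging from wrist accelerometry with actisleep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep staging from wrist accelerometry with actisleep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, the tunable parameters, the synthetic
data generator, and the numerical and design choices behind `actisleep`.
It states no empirical result beyond what the package's test suite and
`scripts/acceptance.R` compute themselves.

## The measurement problem

Polysomnography (PSG) scores sleep in 30-s epochs into five AASM stages —
wake (W), three NREM depths (N1, N2, N3) and REM (R) — from EEG/EOG/EMG.
A wrist accelerometer observes none of those signals; it observes
movement and posture. Movement separates wake from sleep well, separates
REM from deep NREM weakly (REM carries residual muscle twitching, N3
almost none), and separates N1 from N2 hardly at all. Any
accelerometry-based stager therefore faces a graded task: two-class
(wake/sleep) agreement is expected to be far higher than three-class
(wake/REM/NREM), which in turn exceeds five-class agreement. The package
is designed so this ordering is measurable on synthetic data.

## Preprocessing

`preprocess_config()` holds the processing constants, all configurable:

| parameter | default | meaning |
|---|---|---|
| `target_rate` | 30 Hz | resampling target (linear interpolation) |
| `clip_g` | 3 g | clipping bound per axis |
| `epoch_seconds` | 30 s | epoch length (900 samples at 30 Hz) |
| `nonwear_sd_mg` | 13 mg | per-axis stationarity threshold |
| `nonwear_min_minutes` | 60 min | non-wear run length, strict inequality |
| `unrealistic_mean_mg` | 200 mg | exclusion on recording-level ENMO mean |
| `calibration_error_mg` | 30 mg | exclusion on stationary-sphere error |

Choices worth noting:

* **Resampling** is linear interpolation onto the uniform grid anchored
  at the recording start. It is exactly testable (a linear ramp is
  reproduced to 1e-9) and matches common accelerometer toolchains.
* **Partial trailing windows are dropped**, never padded: every
  classified window contains a full 30 s of real signal.
* **Non-wear** flags maximal runs of epochs whose three axis SDs are all
  below 13 mg when the run is *strictly longer* than 60 min (121 epochs
  qualify, 120 do not) — a literal reading of "greater than 60 min".
  Intervals are half-open `[start, end)`, timestamps UTC.
* **"Unrealistic high values (> 200 mg)"** is interpreted as a
  recording-level ENMO-style mean (vector magnitude minus 1 g, floored at
  zero) above 200 mg. A per-sample rule would reject every normal
  recording, and a recording-level mean of 200 mg is far outside the
  physiological range.
* **Calibration** uses a simplified stationary-sphere statistic: the mean
  absolute deviation of the vector norm from 1 g over stationary epochs.
  A full gain/offset re-estimation is out of scope; the statistic flags
  the same gross failures. With no stationary epochs the statistic is
  undefined and recorded as a reason without excluding the recording.

## Time-in-bed detection

The detector mirrors standard actigraphy practice: hand-crafted per-epoch
features, a probability random forest trained on sleep-diary labels, and
a 2-state hidden Markov model smoothing the forest's epoch probabilities.

The feature set (one row per worn epoch): ENMO mean; per-axis mean, SD
and range; vector-magnitude SD; arm angle (z axis against the horizontal
plane) mean and SD; absolute angle change versus the previous epoch; the
fraction of spectral power in the 0.3–3 Hz movement band; and a rolling
5-min median of ENMO. The set is deliberately pluggable — any feature
matrix with an `epoch_start` column works.

The HMM has transition probabilities estimated from the empirical diary
label sequence (Laplace-smoothed, never across subject-night boundaries)
and discrete emissions over 10 equal-width bins of the forest
probability. Decoding is exact Viterbi in log space, verified in the test
suite against exhaustive enumeration of all state paths for sequences up
to length 12. Maximal runs of the in-bed state become windows; windows
separated by at most 60 min are merged transitively; each noon-to-noon
interval keeps its longest window.

Two under-specified corners are fixed as: a window belongs to the
noon-to-noon interval containing its *midpoint*, and ties between equally
long windows resolve to the earliest start. Both choices are arbitrary
but deterministic, and documented here.

## SleepNet

The stager has three parts, all built from scratch in RcppArmadillo with
hand-derived backpropagation (verified by central finite differences at
relative tolerance 1e-4):

1. a **1D-convolutional residual extractor** over each 3 × 900 window:
   a strided stem convolution, then pre-activation residual blocks
   (BN → ReLU → conv → BN → ReLU → conv, with a strided 1 × 1 projection
   shortcut when the shape changes), a final BN/ReLU, and global average
   pooling into a per-window feature vector;
2. a **bidirectional LSTM** over the night's epoch sequence, so each
   epoch's score can depend on its whole-night context;
3. **two fully-connected layers** mapping the concatenated hidden states
   to five stage logits.

Two fixed input features precede the stem: per-window, per-axis mean
removal (the gravity component — about 1 g in an arbitrary orientation —
otherwise dominates the 15–35 mg movement signal), and an appended
vector-magnitude channel, a rectifying feature that gives the first
convolution direct access to the movement envelope. Both are toggleable
(`center_input`, `input_vm`).

The `"tiny"` preset (stem 4→8 stride 4, blocks 8→16 and 16→32 stride 4,
LSTM hidden 24 per direction, FC width 32; ~25k parameters) is the
routine test surface; `"resnet17"` instantiates the full 17-conv-layer
topology with doubling channel widths (64…512) for shape-contract tests.
Everything — kernel sizes, strides, widths, sequence length, dropout,
optimizer settings — is driven by `sleepnet_config()`.

Training uses Adam on class-weighted cross-entropy (inverse-frequency
weights, capped at 10; the weighting is optional), random 64-epoch crops
of nights batched 8 sequences at a time, early stopping on a held-out
subject split, and full-night sequences at inference. Because batch-norm
running averages lag the weights during optimisation, the final model's
normalisation statistics are re-estimated by a few frozen-weight sweeps
over the training nights before any evaluation ("BN recalibration");
without this step the running statistics reflect stale parameters and
eval-mode predictions collapse. Inference is deterministic: running
statistics, no dropout, no RNG.

Cross-validation is subject-wise: `make_folds()` produces a balanced
seeded partition, `train_sleepnet()` refuses fold assignments in which a
subject appears twice, and out-of-fold predictions are returned for every
labelled epoch.

## Self-supervised pretraining

The extractor can be pre-trained without stage labels by discriminating
spatiotemporal transformations: each unlabeled window is independently
subjected (probability 0.5 each) to **time reversal**, **segment
permutation** (4 segments, never the identity permutation) and a
**random monotone time warp** (4 knots, log-normal segment speeds,
resampled back to 900 samples), with one logistic head per task on the
extractor output and a summed binary cross-entropy loss.

Two details matter in practice and are defaults here:

* **Transformations are re-drawn on every visit** of a window, and fresh
  white noise (`jitter_sd`, default 0.02 g) is added per draw. With a
  fixed transformed dataset the network simply memorises each window's
  orientation — training loss collapses while held-out discrimination
  stays at chance. Re-drawing makes the transformation itself the only
  learnable signal.
* The heads can read either the pooled feature vector (`ssl_head =
  "gap"`) or the pre-pooling feature map (`"map"`). Pooling erases
  position, which is irrelevant for reversal (whose signature — the
  asymmetry of fast-attack/slow-decay movement transients — is
  position-free) but in principle informative for permutation.

Known limitation: with the default three-task composition at desk scale,
the time-warp task is learned quickly (warping recolours the noise
spectrum everywhere) and segment-permutation discrimination stays near
chance — its only signature is three boundary discontinuities per window,
which survives neither pooling nor the strided convolutions well. The
package's acceptance battery therefore demonstrates the mechanism on the
single-task time-reversal setting, where held-out AUC exceeds 0.95 on
burst-dense windows, and treats per-task AUC on the joint setting as
diagnostic output rather than a guarantee.

Warm-starting supervised training from pretrained extractor weights is
supported (`pretrained_weights` in `train_sleepnet()`); the package's
tests check the paired comparison that warm starts reach a training loss
no worse than cold starts at a small epoch budget, averaged over seeds.

## Sleep parameters

Within a time-in-bed window: total sleep duration is 30 s × the number of
non-wake epochs; sleep efficiency is total sleep over window duration;
sleep onset is the first non-wake epoch; **WASO counts all wake from
onset to the window end** (no "final awakening" truncation — the
definition is configurable in the sense that the summary exposes onset so
other conventions can be derived); REM/NREM ratios are percentages of
total sleep. An all-wake window reports zero efficiency and WASO 0 with a
`no_sleep` flag. The invariants (REM + NREM = total sleep, ratios sum to
100%, efficiency within [0, 100]) are property-tested on 1000 random
nights against an epoch-counting oracle.

Cohort filters follow the standard inclusion rules: at least 3 calendar
days with at least 22 h of wear, at least one valid weekday and one
weekend day (Saturday/Sunday of the night's local calendar date), and
metadata-driven exclusion of shift workers and daylight-saving
crossovers (these two operate on flags supplied with the cohort, since
questionnaire data is not part of this package's inputs).

## Agreement evaluation

Cohen's kappa uses chance agreement from the marginals; "F1" means
macro-averaged F1 (per-class values are also emitted); balanced accuracy
is the mean per-class recall. Epoch-pooled and subject-wise summaries are
both computed and labelled; subjects whose truth contains a single class
are excluded from the kappa mean and flagged. Bland-Altman limits of
agreement use the normal-theory multiplier 1.96 with differences defined
as estimate − reference, so positive bias means overestimation; no
repeated-measures correction is applied because validation uses one night
per subject. Metrics are verified to 1e-12 against independent
brute-force formula evaluation on hundreds of random confusion matrices.

## Wear-time simulation

`apply_wear_mask()` removes random contiguous 1-h blocks (device
non-wear is contiguous in practice) until each retained day keeps exactly
the scheme's hours, and masks non-retained days entirely. The weekly
estimate under masking is the mean over retained days of per-day
overnight sleep duration. Stability is measured by ICC(2,1) — two-way
random effects, absolute agreement, single measure — between masked and
complete estimates; the implementation is checked against explicit ANOVA
sums of squares and against the closed form σ²~b~/(σ²~b~+σ²~e~) on
simulated variance components. `wear_grid_search()` reports the full
(hours × days) grid and the minimal cell exceeding the ICC threshold
(default 0.75). Which cell that is depends strongly on the ratio of
between-subject variance to masking error; the package reports the grid
rather than asserting any particular minimum.

## The synthetic cohort generator

The generator is first-class, tested code; its defaults define the
study conditions used throughout the tests.

**Stage dynamics.** A first-order Markov chain over the five stages at
30-s resolution (`default_stage_model()`), so stage dwell times are
geometric — a deliberate simplification (no semi-Markov bout-length
model) that keeps the stationary distribution analytic: the test suite
checks simulated stage frequencies against the transition matrix's left
unit eigenvector. The default matrix gives sustained N2/N3/REM bouts,
brief N1, ~11% wake after onset and roughly a sixth of sleep in REM.
Bed timing: bedtime 23:00 ± 30 min and time in bed 8 h ± 30 min night to
night, with additional between-subject habitual offsets of ± 45 min SD
each — population heterogeneity of habitual sleep on the order reported
for large adult cohorts (total SD ≈ 0.9 h).

**Signal model.** Per epoch, the signal is a unit-norm gravity vector —
piecewise constant between posture-shift events (Poisson, stage-dependent
rate), each shift rotating the vector by a random-axis angle — plus
stage-dependent white noise and movement bursts. Bursts are damped
directional transients: a fast-attack (20% of duration) exponential-decay
envelope carrying both a sustained directional component and an
oscillation (0.8–3 Hz). The envelope makes the signal asymmetric in
time, which is what the time-reversal self-supervision task detects; the
directional component reflects that real arm movements produce net
acceleration along a path, not zero-mean vibration. Noise SDs
(W 33, R 18, N1 16, N2 15.3, N3 15, ambulatory wake 60 mg) sit just
above the 13 mg stationarity threshold so worn sleep is never mistaken
for non-wear, and order movement energy W ≫ R > N1 > N2 > N3 — strong
sleep/wake separability, weak REM/NREM separability.

**What the generator does not emulate**: EEG-defined stage content
(posture and movement are the *only* stage signals, so absolute staging
accuracy on synthetic data says nothing about accuracy on real sleepers);
circadian modulation of stage probabilities across the night; apnoea or
periodic limb movements; device axis miscalibration drift; shift-work or
daylight-saving patterns. Passing tests therefore demonstrate that the
pipeline's machinery is correct and that its qualitative orderings hold
under the stated movement physiology — not that any particular agreement
level transfers to real populations.

**Diaries and non-wear.** Diary times are the true sleep onset/offset
plus uniform(−15, +15) min self-report noise. Injected non-wear gaps are
constant-gravity, zero-noise intervals placed in the evening out-of-bed
period and recorded as ground truth.

## Problem sizes

The routine evaluation cohort is 20 subjects × 2 nights × 120 epochs
(1 h of in-bed signal per night) with the tiny preset and five folds;
self-supervision runs use 12 subjects × 200 burst-dense windows; the
wear-time grid uses label-level weeks (no raw signal), which makes the
masking loop essentially free. These sizes keep the whole test suite and
the acceptance script within a few minutes on a single CPU while leaving
every contract measurable; all of them scale up by changing one argument.

## Known limitations

* Stage dwell times are geometric; real bout-length distributions are
  heavier-tailed.
* The calibration statistic is a screen, not a re-calibration.
* Segment-permutation self-supervision is structurally weak at this
  scale (see above).
* The wear-time grid's minimal cell is a property of the synthetic
  variance structure, not a reusable clinical recommendation.
* The Cox-regression mortality analysis that such sleep parameters feed
  into downstream is out of scope here.
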