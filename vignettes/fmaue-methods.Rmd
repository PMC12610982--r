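---
title: "Estimating FMA-UE sub-scores from wearable IMU data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating FMA-UE sub-scores from wearable IMU data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

The Fugl-Meyer Assessment of the Upper Extremity (FMA-UE) is the standard
clinician-rated scale of post-stroke motor impairment. It decomposes into
four parts -- A: shoulder/elbow (0-36 points), B: wrist (0-10), C: hand
(0-14), D: coordination and speed (0-6) -- summing to a total of 0-66.
Administering it requires a trained therapist, which limits how often a
patient's recovery can be tracked.

`fmaue` implements a pipeline that estimates the four sub-scores from
inertial measurement unit (IMU) recordings of seven short, specialized
upper-limb motions: reaching upward (RU), reaching the contralateral knee
to the ipsilateral ear (RKE), hand to lumbar spine (HTS), elbow
pronation-supination (EPS), wrist circumduction (WC), hand mass
flexion-extension (HMFE), and reaching knee to nose (RKN). The first four
chiefly probe part A (the `A*` group); WC, HMFE and RKN probe parts B, C
and D (`B*`, `C*`, `D*`). Four IMUs are worn on the hand, forearm, upper
arm and trunk; each reports 3-axis acceleration (within +/- 8 g), angular
rate (within +/- 2000 deg/s) and orientation at a nominal 100 Hz, and all
segments are zero-referenced against a stationary neutral pose recorded at
the start of a session.

Because clinical recordings of this protocol are not publicly available,
the package ships a synthetic cohort simulator with controllable,
impairment-graded structure, so that every pipeline stage -- and the
estimator's ability to recover impairment from signals -- can be tested
end to end without any external data.

## The synthetic cohort model

A subject is described by a severity vector $s = (s_A, s_B, s_C, s_D) \in
[0,1]^4$ (0 = unimpaired); the ground-truth sub-score of part $k$ is
$\mathrm{round}((1 - s_k)\,\mathrm{range}_k)$. The default severity
sampler draws each component independently from Beta(2, 2) and makes a
subject entirely healthy with probability 0.2, mirroring a cohort in
which roughly a fifth of participants are unimpaired controls and the
rest span the impairment range.

Each motion couples the severity components through fixed weights
(`motion_specs()`): the dominant part carries weight 0.7 and the
remaining 0.3 is assigned to the other parts the motion touches; a motion
that touches only its dominant part gets weight 1. With
$w \cdot s$ the coupling-weighted severity of a trial, the simulator
generates, per segment and axis:

* a base trajectory of five repetitions of a minimum-jerk-profile
  oscillation (position profile $10\tau^3 - 15\tau^4 + 6\tau^5$ per
  half-stroke), with amplitude $A_0\,(1 - 0.8\,w\cdot s)$ and repetition
  period $T_0\,(1 + w \cdot s)$ -- impaired movement is smaller and
  slower, and trials of impaired subjects are correspondingly longer at a
  fixed repetition count;
* additive band-limited (3-8 Hz) tremor on the orientation channels with
  standard deviation proportional to $w \cdot s$ (2 degrees at full
  coupling-weighted severity);
* gyro as the time derivative of orientation, and acceleration as the
  gravity component along the segment axes plus a movement term and white
  sensor noise (0.01 g accelerometer, 0.5 deg/s gyro floors).

An unimpaired trial (all severities 0) nominally lasts 10 s (5
repetitions x 2 s), which at 100 Hz with 2 s windows and 50% overlap
yields exactly 9 windows -- the default tensor depth `wl = 9`.

What the simulator deliberately does **not** model: biomechanically exact
limb kinematics, compensatory trunk strategies, sensor drift,
magnetometer disturbance, or inter-trial variability in motion strategy.
Passing recovery tests on this cohort therefore demonstrates that the
pipeline extracts and regresses the impairment signatures it was designed
around (amplitude, smoothness, tremor, speed), not that it attains any
particular accuracy on real patients.

## Preprocessing

Per channel (raw IMU streams and the nine joint angles alike):

1. **Outlier replacement** -- Hampel-style: samples more than
   `z_thresh = 3` robust standard deviations ($1.4826\,\mathrm{MAD}$)
   from the median are replaced by the mean of the inliers. A constant
   channel (MAD 0) is passed through unchanged by convention.
2. **Zero-phase Butterworth filtering** -- applied forward-backward, so
   no phase distortion. Two named presets ship. The `"paper"` preset
   (high-pass 10 Hz + low-pass 49.9 Hz, order 4) reproduces a 10-50 Hz
   band-pass at 100 Hz sampling literally; note that its upper corner
   sits at Nyquist and it removes the sub-10 Hz band where voluntary
   upper-limb motion lives. The `"functional"` preset (0.25-10 Hz,
   order 4) keeps the motion band while removing drift and mains-range
   interference, and is the default for synthetic-recovery work. Both
   are realized as a high-pass/low-pass cascade, which is numerically
   robust for corners far below Nyquist; reports name the preset used.
3. **Resampling to 100 Hz** -- linear interpolation onto a uniform grid
   spanning the recording.

**Joint angles.** For each adjacent segment pair (hand-forearm = wrist,
forearm-upper arm = elbow, upper arm-trunk = shoulder), the relative
rotation $R_{\mathrm{rel}}(t) = R_{\mathrm{prox}}(t)^{-1}
R_{\mathrm{dist}}(t)$ is re-referenced by the neutral sample so the
angles start at zero, then decomposed with an intrinsic Z-Y-X Euler
sequence. The decomposition order is a declared convention (the anatomy
names axes, not an order); the 90-degree single-axis fixtures in the test
suite pin it down.

**Signal-level augmentation** produces extra training copies per trial
by applying, in order: additive Gaussian noise (sigma = 5% of each
channel's SD), a single global time-warp factor drawn from [0.9, 1.1]
with cubic re-interpolation back onto the uniform grid, and amplitude
scaling about the per-channel mean with a factor drawn from [0.8, 1.2].
The warp and amplitude factors are shared across channels of a copy so
the copy remains kinematically coherent. Copies are generated with
per-subject seeds that do not depend on any cross-validation fold
structure, so a subject's copies are computed once; they are used for
training only when the subject is in the training fold, and as the
subject's multiple test samples (mean-aggregated) when it is held out.

**Windowing** cuts each motion, after augmentation, into 2 s windows
with 50% overlap; the trailing partial window is dropped.

## The 1530-dimensional feature registry

The published feature count (1530 per window) is decomposed here as 153
channels x 10 statistics. This registry is a declared convention chosen
to (a) include every channel family the protocol names and (b) hit the
printed total exactly; it is versioned and data-driven
(`feature_registry()`), so an alternative decomposition totalling 1530 is
a drop-in replacement.

Channels, per IMU segment (x4): acceleration, gyro, orientation,
orientation acceleration (second difference of orientation x rate^2),
angular difference (first difference x rate), and inclination ratio
(trunk-relative orientation) -- each on 3 axes and each paired with its
first-difference counterpart (36 per segment) -- plus the nine joint
angles: 4 x 36 + 9 = 153. The inclination ratio is neutral-referenced on
both ends (segment and trunk), so it is zero at the neutral pose and
zero whenever a segment tracks the trunk exactly.

Statistics, per channel: mean, population standard deviation, RMS,
amplitude ((max - min)/2), max, min, range (max - min), approximate
entropy, median, and interquartile range. ApEn follows the classical
definition (self-matches included, Chebyshev distance) with $m = 2$ and
$r = 0.2\,\sigma$ of the window channel; a constant channel has ApEn 0.
The kernel is C++ for speed and is checked against a naive brute-force
oracle to 1e-10 in the test suite.

Per subject, the seven motions' window features are assembled into a
`[7, wl, 1530]` tensor. A motion with more than `wl` windows is cropped
centrally; one with fewer is padded by repeating its last window, and
padded slots are recorded in a mask that excludes them from the
encoder's temporal pooling.

## The estimator

Features are z-scored per feature index with statistics fitted on the
training fold only; scores are divided by the part ranges (36, 10, 14,
6) into [0, 1]. Training minimizes MSE on the normalized scale so no
part dominates the loss; predictions are mapped back and clipped to the
valid range only at reporting time.

**Mixup.** With probability `apply_prob` (default 1) a training batch is
replaced by a convex combination of itself with a random within-batch
permutation: $\hat{x} = \lambda x_i + (1-\lambda) x_j$, $\hat{y} =
\lambda y_i + (1-\lambda) y_j$, $\lambda \sim \mathrm{Beta}(\alpha,
\alpha)$ with $\alpha = 1$ (i.e. uniform). One $\lambda$ is drawn per
batch -- the standard realization of per-pair mixing. Setting
`apply_prob = 0` gives the exact no-mixup ablation arm. Where two mixed
samples disagree on which window slots are padded, the mixed mask is the
union of the parents' masks (padded slots contain repeated real windows,
not garbage, so pooling over a slot valid in either parent is
well-defined).

**Architecture.** A single LSTM (hidden width 256) is shared across the
seven motions and run over each motion's window sequence; the hidden
states are mean-pooled over the real windows and projected linearly to a
128-dimensional per-motion latent, giving `[7, 128]`. A second LSTM
(hidden width 128 -- the latent width is maintained) consumes the seven
latents as a sequence in the fixed motion order; its final hidden state
passes through dropout (p = 0.3, training only) and a linear head to the
`[1, 4]` output. Sharing the encoder across motions is a declared
design choice (the parameter-efficient reading of a single encoder
layer); motion order is part of the model contract, as the predictor is
order-sensitive.

**Training.** Adam (conventional betas, no weight decay, no schedule) at
learning rate 5e-5 for 100 epochs, batch size 8, all seeded: parameter
initialization is the conventional uniform(-1/sqrt(hidden),
1/sqrt(hidden)) of dense recurrent layers, and shuffling, mixup draws
and dropout masks all derive from the training seed, so loss histories
are bit-reproducible on one machine. The LSTM forward pass and full
backpropagation through time are implemented in the package as batched
BLAS matrix algebra; the analytic gradients are verified against central
finite differences in the test suite, which is the correctness anchor
for the whole training loop. A NaN loss aborts with the epoch named.

## Evaluation

**LOSOCV.** With $n$ subjects the model is trained $n$ times, each time
re-initialized, with normalization refitted on the training fold only;
the held-out subject's samples (original + augmented copies) are
predicted and mean-aggregated. Training and test are disjoint by
subject; fold seeds derive deterministically from the master seed, so
ablation arms are paired across identical fold randomness.

**Metrics.** Per part and for the total (sum of parts, divisor 66):
$R^2 = 1 - SS_{res}/SS_{tot}$ over subjects, Pearson r with a two-sided
test, MAE, RMSE, NMAE = MAE/range and NRMSE = RMSE/range. The "overall"
row pools the range-normalized pairs of all parts. A constant truth
makes r undefined and it is reported as `NA`, never NaN. The
range-divisor convention reproduces the published per-part NMAE values
from their MAE counterparts to four decimal places; the published NRMSE
values for parts A and D are not consistent with any single divisor
(they imply approximately 32 and 4.45 against exactly 10 and 14 for B
and C), so the package applies the range divisor uniformly and documents
the discrepancy rather than guessing the original normalization.
Likewise, the published "overall" weighting is undefined in the source
material; pooled range-normalized pairs are the declared convention
here.

**Ablation** re-runs the full LOSOCV with the tensor's motion axis
restricted to a named subset (`ablation_presets()` gives the full set
and the four drop-one-group sets); the model input is resized
accordingly.

**Motion contribution** (the method behind per-motion importance maps is
not specified in the source material; permutation importance is the
declared stand-in, and outputs are labelled as such): for motion m and
part k, the mean increase in absolute part-k error when motion m's
tensor rows are permuted across subjects, averaged over repeats,
negatives floored at zero, and normalized per part to sum 1 over
motions. An all-zero part is left unnormalized and flagged.

## Numerical choices and degenerate inputs

* Population (divide-by-N) standard deviation throughout the feature
  statistics; amplitude and range are deliberately distinct statistics.
* Feature SDs are floored at 1e-8 before z-scoring, so constant features
  map to 0 rather than NaN.
* A constant series passes outlier replacement unchanged; a series whose
  samples are all flagged is returned unchanged with a warning.
* Interpolation at the trailing grid point clamps to the last sample to
  avoid extrapolation NaN from floating-point grid arithmetic.
* A gimbal-degenerate neutral pose (|pitch| = 90 degrees in the relative
  rotation) aborts joint-angle computation naming the joint.
* Mixed-motion trials shorter than one window abort windowing; a motion
  with zero windows aborts tensor assembly.

## Problem sizes used by the shipped evaluations

The package's own evaluation runs (the recovery test in the suite and
`scripts/acceptance.R`) use a 15-subject synthetic cohort at 100 Hz, the
functional filter preset, one augmented copy per trial, 30 training
epochs per fold, and default model dimensions (1530/256/128). These
sizes are the package's chosen evaluation scale: large enough that the
estimator must genuinely learn the impairment mapping (about 10 minutes
of single-threaded compute for 15 folds), small enough to re-run
routinely. The directional-ablation check uses a deliberately small
planted cohort (8 subjects, 50 Hz, reduced model widths) because only
the sign of the degradation is asserted, not its magnitude. Per-part
$R^2 \ge 0.6$ at larger cohort sizes and full 100-epoch training is an
extended bar beyond this routine scale and is not exercised by the
default suite.

## Known limitations

* The synthetic generator is the package's own model of impairment; its
  parameter defaults (amplitudes, periods, tremor gain, noise floors)
  are plausible-magnitude choices, not fitted to clinical data.
* The 153 x 10 registry is one decomposition of the published feature
  count; the original channel/statistic breakdown is not recoverable
  from the source material.
* Orientation is taken as given (as in the measurement protocol);
  sensor-fusion estimation from raw accelerometer/gyro data and drift
  correction beyond neutral-pose referencing are out of scope.
* Training at the published 100-epoch/5e-5 setting on real-size cohorts
  is compute-intensive in this pure-R implementation; the shipped
  evaluations reduce epochs to 30, which is sufficient for the
  recovery properties asserted.
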