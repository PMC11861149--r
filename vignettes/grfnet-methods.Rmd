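---
title: "Predicting running vGRF curves from joint angles: models and methods"
author: "grfnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting running vGRF curves from joint angles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During the stance phase of running -- from initial heel contact to toe-off
-- the ground exerts a vertical reaction force (vGRF) on the foot whose
curve, under a rear-foot strike, shows two peaks: a sharp *impact* peak
shortly after touch-down and a broader *active* peak near mid-stance.
Measuring this curve normally requires laboratory force plates. `grfnet`
implements an alternative: regressing the whole 101-point stance-phase vGRF
curve from lower-limb joint-angle time series (ankle, hip and knee, each in
the sagittal, frontal and transversal plane), the kind of signal a wearable
IMU suit or markerless video pipeline can deliver outside the lab.

The package covers the complete workflow: a synthetic gait generator (so
every stage is testable without human data), the standard biomechanical
preprocessing chain, four trainable sequence-to-curve networks built around
the extended-LSTM family, and a cross-validated evaluation harness.

## The models

All four architectures share the same skeleton:

1. **CNN front end.** A same-padded 1-D convolution along stance time
   (kernel size 3, 32 filters, ReLU), followed by max pooling of size 2.
   The 101-point input sequence becomes a 50-step feature sequence; the
   pooled sequence is the input of the recurrent stack.
2. **Recurrent stack**, one of:
   - `lstm`: the vanilla cell, `C_t = f_t C_{t-1} + i_t z_t`,
     `h_t = o_t tanh(C_t)`, with sigmoid gates and tanh candidate;
     two stacked layers of 128 units by default.
   - `slstm`: the scalar extended-LSTM cell. Input and forget gates pass
     through the exponential rather than the sigmoid, and a *normalizer
     state* `n_t = f_t n_{t-1} + i_t` accumulates gate mass; the readout is
     the normalized cell `h_t = o_t (c_t / n_t)`. Exponential gates are
     unbounded, so the implementation keeps them in a log-domain stabilized
     form with a running max-shift `m_t`; the ratio `c_t / n_t` is exactly
     invariant to the shift, which is why the stabilized recursion
     reproduces the textbook form (a tested invariant) and why `m_t` can be
     treated as a constant during backpropagation.
   - `mlstm`: the matrix-memory extended-LSTM cell. Each unit row of a
     square `H x H` memory is written through
     `C_t = f_t (*) C_{t-1} + i_t (*) tanh(W_c [h_{t-1}, x_t] + b_c)` with
     gates broadcast row-wise, and read out through a learned query
     `q_t = W_q x_t + b_q` as `h_t = C_t q_t / max(n_t' q_t, 1)`. The
     normalizer `n_t` follows the same recurrence as in the sLSTM, and the
     denominator clamp at 1 keeps the readout bounded before the
     normalizer has accumulated mass.
   - `xlstm`: the hybrid -- an mLSTM block feeding an sLSTM block
     (module order `'m', 's'`).
3. **Output head.** The recurrent output sequence is flattened and mapped
   by one dense layer onto the 101-point curve.

Defaults follow the model-configuration table used throughout: batch 128,
hidden size 64, 25 epochs, one stacked layer for the three extended
variants; batch 256, hidden 128, 55 epochs, two layers for the vanilla
LSTM. Training minimizes mean-squared error with Adam (lr `1e-3` by
default); loss and optimizer settings are exposed through `grfnet()`
arguments since the choice is not dictated by the architecture.

Design points that were genuinely open, and how they were resolved:

- **mLSTM geometry.** The printed matrix-memory update does not fix the
  memory's shape. We use a square `H x H` memory: with rows indexed by
  hidden unit, the row-wise gate broadcast, the `R^H` normalizer recurrence
  and the `n_t' q_t` readout denominator are mutually consistent without
  extra projections. Gates are sigmoid (the exponential gating is the
  sLSTM's defining feature); the candidate is the tanh of a learned linear
  map of `[h_{t-1}, x_t]` as printed, not the key/value outer product used
  elsewhere in the literature.
- **sLSTM candidate.** The cell update reuses the vanilla form
  `c_t = f_t c_{t-1} + i_t z_t` with tanh candidate `z_t` and sigmoid
  output gate; only `i_t` and `f_t` are exponential.
- **Gradient of the stabilizer.** `m_t` is a stop-gradient. Because the
  readout is invariant to `m_t`, analytic gradients are exact wherever the
  running max is locally constant; finite-difference checks in the test
  suite confirm agreement to better than `1e-4`.
- **Backends.** The batched layer forward/backward passes are
  RcppArmadillo kernels; plain-R single-sample step functions
  (`lstm_step()`, `slstm_step()`, `mlstm_step()`) are the readable
  reference, and the tests force both routes to agree sample-by-sample.

## Preprocessing chain

`preprocess_trial()` applies, in order:

1. **Filtering.** Zero-phase fourth-order Butterworth low-pass: 10 Hz
   cutoff on the 1000 Hz force channel, 20 Hz on the 200 Hz angle
   channels. Zero-phase (forward-backward) filtering is the biomechanics
   convention because it does not lag peak timings; the price is a squared
   amplitude response, i.e. roughly doubled attenuation in dB. The
   implementation initializes each pass in the steady state of the first
   sample and pads by odd reflection, so a constant series passes through
   exactly and edge transients stay out of the stance window. One
   consequence worth knowing: a 10 Hz cutoff smooths the ~20 ms impact
   transient considerably, so the *filtered* target curves can show the
   impact peak as a shoulder rather than a distinct maximum.
2. **Stance segmentation** on the filtered force with the 10 N rule:
   the window starts at the first sample strictly above 10 N and ends at
   the first subsequent sample at or below it (half-open `[start, end)`,
   0-based). Sub-threshold dips shorter than 5 ms are bridged so chatter
   does not split a stance. Detection runs after filtering because the
   filtered signal crosses the threshold cleanly.
3. **Time normalization.** Each channel inside the window is linearly
   interpolated onto 101 points spanning 0..100% of stance. Linear
   interpolation is the standard for gait time normalization, is
   endpoint-exact, and makes the operation idempotent.
4. **Unit conversion.** The force target becomes body weights
   (`force / (mass x g)`, `g = 9.81`), the conventional unit that makes
   curves comparable across subjects.
5. **Dataset assembly.** The nine channels are flattened channel-major in
   a fixed joint-major order (ankle, hip, knee x sagittal, frontal,
   transversal) and subset into seven factorizations: `M1` (all 9
   channels, 909 columns), `M2`-`M4` (one joint, 3 planes, 303 columns),
   `M5`-`M7` (3 joints, one plane, 303 columns).

Min-max scaling (`x' = (x - min) / (max - min)` per feature) is *not* part
of dataset assembly: it is fit inside each training fold and reused on the
test fold, because fitting it on all data would leak test information into
training. Constant features map to 0 with a warning rather than failing,
which keeps degenerate synthetic configurations usable. No outlier
rejection is applied anywhere: trials pass through unless the chain cannot
process them (no stance above threshold, or too few samples in the
window), in which case they are dropped with a message.

## The synthetic gait generator

No public dataset accompanies the task, so `generate_gait_dataset()`
emulates the study conditions: 530 trials cycled round-robin over the five
nominal speeds (8-16 km/h, 106 trials each) and over 12 synthetic
subjects whose body masses are drawn once from N(72.5, 9.55^2) kg, the
anthropometrics of a young male runner cohort.

- **Angles.** Each of the 9 channels is a sum of up to four half-cycle
  cosines in stance fraction `u`, `theta(u) = a0 + sum ak cos(k pi u)`,
  evaluated on a 200 Hz grid plus Gaussian noise (default sd 0.5 deg).
  Coefficients vary linearly with speed, and sagittal amplitudes dominate
  the out-of-plane channels, as in stance-phase running kinematics.
- **vGRF.** Body weight times a double-peak template (two asymmetric
  Gaussian bumps: impact peak at 13% of stance, default height
  `1.35 + 0.055 v` BW; active peak at 45%, `2.10 + 0.05 v` BW) plus a
  quadratic coupling to the noise-free sagittal ankle and knee curves
  (gain 0.2 BW, windowed by `sin^2(pi u)`), tapered to zero over the
  outer 3% of stance, padded with 50 ms of zero force on each side,
  noised (default sd 0.02 BW) and clipped at 0 N. The coupling guarantees
  that the regression target carries angle information beyond the
  template mean; `vgrf_peak_bound()` reports the exact bound by which
  sampled peaks may deviate from the configured magnitudes.
- **Inter-trial variability.** Peak magnitudes and timings are jittered
  by +/-10% (uniform) per trial and the stance duration by +/-8%, so
  stance lengths vary and the 10 N segmentation is genuinely exercised.
  Stance duration defaults to `0.340 - 0.009 v` seconds, shortening with
  speed as observed in runners.

What the generator does *not* emulate: musculoskeletal dynamics, swing
phases, anterior-posterior or medio-lateral force components, left/right
asymmetry, surface or footwear effects, and -- importantly -- any coupling
between the jitter and the angles. The jittered peak parameters are drawn
independently of the inputs, so a fraction of the inter-trial variance is
irreducible for *any* regressor; passing tests therefore demonstrate that
the pipeline recovers what is recoverable under its own generative
assumptions, not that the networks would reach the same accuracy on real
runners.

## Evaluation protocol

`cv_grfnet()` shuffles the trials by seed, splits them into K = 10 folds
whose sizes differ by at most one (exactly 53 with 530 trials), and for
each fold fits min-max parameters on the training rows only, trains the
model on the scaled data, and evaluates on the held-out fold. Metrics:

- `r_squared()`: `1 - SSE/SST`, computed per test curve and averaged
  (pooled computation available via `pooled = TRUE`). Curves with constant
  truth are dropped with a warning.
- `mape()`: mean absolute percentage error over points with `|y|` at or
  above a floor (default 0.05), which keeps the near-zero samples at
  touch-down and toe-off from inflating the percentage; the floor is an
  argument and is logged in the report.
- `rmse()`: the square root of the mean squared residual. The root is
  taken deliberately -- the printed error magnitudes of this family of
  studies (≈0.06-0.2 for body-weight curves) are only consistent with a
  root-mean-square, not a mean-square.

**Evaluation scale.** Models train on min-max-normalized targets, but
metrics are computed on the body-weight scale by default
(`metrics_scale = "bw"`; predictions are inverted with the training-fold
parameters). The reason is structural: per-feature min-max scaling maps
every stance-percent column to [0, 1], which removes the double-peak shape
shared by all trials. On that scale, the per-curve variance is almost
entirely irreducible inter-trial jitter, and even the ideal
conditional-mean predictor scores a per-curve R^2 at or below zero -- no
model can look good or bad there in a way that reflects curve recovery.
On the BW scale the per-curve R^2 measures what practitioners mean by
"fitting the vGRF curve". `metrics_scale = "normalized"` is available for
completeness.

Fold summaries report mean and sample (n-1) standard deviation.
`experiment_grid()` runs all requested architectures over all requested
datasets (the full grid is 4 x 7 = 28 cells) and then re-evaluates the
four strongest input cases (`M1`, `M2`, `M5`, `M6` by default) separately
at each of the five speeds (20 more cells), writing tidy CSV and JSON
reports.

## Problem sizes and schedules used by the shipped checks

Training the three extended variants to their 25-epoch defaults over the
whole grid is a multi-hour computation. The shipped test suite and
`scripts/acceptance.R` therefore use a shortened schedule for the
cross-validated end-to-end checks: 7 epochs at Adam lr `3e-3` (the higher
rate compensating the shorter schedule), with everything else at the
architecture defaults (batch 128, hidden 64, one `'m','s'` layer). On the
noiseless 530-trial cohort this schedule reaches the accuracy of the
speed-conditional-mean predictor (per-curve R^2 ≈ 0.96 on the BW scale),
which is the ceiling imposed by the generator's independent jitter, so
longer training cannot add much. Unit tests run on far smaller instances:
4-25 trials, hidden sizes 3-6, and 5-step rollouts for the
finite-difference gradient checks.

## Known limitations

- The mLSTM follows the printed tanh-candidate matrix update; it does not
  implement the covariance (key/value outer-product) memory of the wider
  xLSTM literature, and no claim is made that the two coincide.
- The vanilla LSTM completes the printed cell recurrence with the standard
  `h_t = o_t tanh(C_t)` output; other completions exist.
- The 10 Hz force filter smooths the impact transient; analyses that care
  about impact-peak magnitude should raise the cutoff
  (`force_cutoff_hz` in the run config).
- Min-max fitting per training fold is one defensible reading of the
  normalization step; fitting on the full dataset (leakier but sometimes
  done) would change reported numbers slightly.
- The synthetic cohort's irreducible jitter caps attainable accuracy at
  the conditional-mean ceiling; real joint-angle data carry trial-specific
  kinematic information the generator deliberately withholds from the
  inputs, so results on real data can differ in either direction.
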