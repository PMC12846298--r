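---
title: "Validating paired wearable recordings: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating paired wearable recordings: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wearval)
```

# The problem

Low-cost wearable devices that record surface EMG and inertial orientation
during activities of daily living have to be validated against laboratory
gold standards before their numbers can be trusted in rehabilitation or
movement research. The canonical study design records the same task twice
with the device and with a reference system — a laboratory EMG amplifier for
muscle amplitude, an optical motion-capture system for segment orientation —
and quantifies agreement per muscle (or per rotational axis) and per limb
with a standard battery: Bland–Altman bias and 95% limits of agreement,
Pearson correlation, the two-way random-effects absolute-agreement
single-measures intraclass correlation ICC(2,1), and coefficients of
variation across task repetitions.

`wearval` implements both measurement chains and the full battery as a
tested, reusable pipeline, and pairs them with a seeded synthetic generator
of paired recordings with known ground truth. Raw recordings from such
studies are rarely deposited; the generator stands in for them so that every
stage — segmentation, filtering, resampling, alignment, statistics — can be
exercised end to end and checked against truth values the generator knows
exactly.

# The EMG amplitude chain

Both systems' recordings go through the identical chain
(`run_emg_pipeline()`):

1. ADC counts to volts, mid-scale referenced:
   `v = (raw / (2^bits - 1) - 0.5) * vref / gain`.
2. Mean-offset correction, then full-wave rectification.
3. A 1 s moving-average envelope.
4. Per-cycle split on video-derived annotations (half-open windows).
5. Resampling of each cycle to 1700 points by mirror padding.
6. Per-cycle normalization to [0, 1].
7. The mean of the five normalized repetitions, summarized by its RMS.

One scalar per participant, side, muscle and system enters the agreement
battery; the RMS of each individual normalized cycle is kept as the
per-repetition value behind the intra-device ICC and the CV.

Two consequences of this construction are worth spelling out. First, the
per-cycle 0–1 normalization makes the final RMS invariant to any positive
affine transform of the raw signal, so the ADC constants (`12` bits,
`3.3` V, gain `1000` by default) are configuration, not substance: any
consistent choice yields identical agreement results (this invariance is a
unit test). Second, the order of operations matters — rectification must
precede the moving average (the envelope of zero-mean noise is strictly
positive), and normalization is per cycle, before averaging across
repetitions.

## Numerical choices

* **Moving-average edges.** The 1 s window is centered and the signal is
  extended by reflection at both ends. Zero padding would droop the envelope
  at the cycle boundaries and corrupt the per-cycle min/max that the
  normalization uses.
* **Mirror-pad resampling.** The cycle `x` is extended to
  `[rev(x), x, rev(x)]`, linearly resampled to `3 * 1700` points, and the
  central 1700-point block is returned. This realization is exactly the
  identity when the cycle already has 1700 samples, which pins down an
  otherwise ambiguous "central window" choice.
* **Degenerate cycles.** A constant cycle cannot be normalized; it maps to
  all zeros and carries a flag rather than NaNs.

# The kinematics chain

The IMU reports segment orientation as Euler angles; the optical reference
provides per-frame 3×3 rotation matrices of the segment relative to the
laboratory. `run_kinematics_pipeline()` harmonizes them:

1. The Euler stream is converted to rotation matrices under one fixed
   convention — intrinsic yaw–pitch–roll (z–y′–x″), degrees:
   `R = Rz(yaw) Ry(pitch) Rx(roll)`. The convention is a free choice; using
   the same one for both systems cancels it in the ROM comparison.
2. A fixed rigid alignment between the IMU frame and the camera's segment
   frame is estimated by orthogonal Procrustes on SO(3): the rotation `A`
   minimizing `sum_t ||R_cam(t) - R_imu(t) A||_F^2`, from the SVD of
   `sum_t R_imu(t)' R_cam(t)` with determinant correction. A rigidly
   mounted sensor has one unknown mounting rotation, hence the one-sided
   (post-multiplied) formulation rather than a two-sided hand–eye problem.
   The alignment is estimated per trial, the most conservative reading of a
   per-study/per-trial ambiguity; a run can instead assert identity
   alignment via `alignment = "identity"`.
3. Both streams are referenced to an initial pose: the chordal mean rotation
   of the first 0.3 s, composed as `R_rel(t) = t(R0) R(t)` so the initial
   pose maps to identity. (The alternative `R(t) t(R0)` changes the Euler
   decomposition; one side had to be fixed, for both systems.)
4. Relative angles are extracted per axis, unwrapped (consecutive steps
   folded into (−180°, 180°]), smoothed by a zero-phase 4th-order
   Butterworth low-pass, resampled to 1700 points per cycle, and reduced to
   per-cycle range of motion, `max - min`.

Axis 1/2/3 are the roll/pitch/yaw components of the relative orientation;
their anatomical gloss (abduction–adduction, flexion–extension,
lateral–medial rotation) is configuration, not computation.

## Numerical choices

* **Butterworth cutoff 6 Hz** by default — a conventional band for
  volitional upper-limb movement, and configurable because the choice is not
  dictated by the chain itself. Filtering is zero-phase (forward–backward)
  so the smoothing adds no lag that would bias per-cycle extrema.
* **Filter edge handling.** A direct forward–backward pass has startup
  transients severe enough to distort short cycles (`signal::filtfilt` pads
  only a few zeros). The signal is therefore extended by odd reflection
  about its endpoints, long enough for the filter's slowest pole to decay
  below 1e-8, and trimmed after filtering; a constant signal passes through
  exactly.
* **Staying on SO(3).** Averaged or accumulated matrices are projected back
  onto SO(3) by SVD with determinant correction; trajectory containers
  validate orthonormality at 1e-6.
* **Gimbal lock.** Within 0.1° of |pitch| = 90° the roll/yaw split is
  undefined; roll is set to 0, the freedom folded into yaw, and the sample
  flagged. The synthetic protocol keeps excursions far from lock.

# The agreement battery

For each target (muscle or axis) and limb, with `n` participants:

* **Bland–Altman**: differences `d = device - reference` (so positive bias
  means the prototype overestimates — the direction had to be fixed and is
  documented rather than implied); bias `= mean(d)`; 95% limits
  `bias ± 1.96 sd(d)` with the sample SD. The 1.96 multiplier (not a
  t-quantile) matches the symmetric-about-bias convention of published
  validation tables, and the LOA midpoint equals the bias exactly — an
  identity the report checks for published tables too.
* **Pearson r** between the paired headline values.
* **ICC(2,1)** on the `n × 2` subjects-by-systems matrix: with mean squares
  MSR (rows), MSC (columns), MSE from the two-way ANOVA decomposition,
  `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`, `k = 2`.
  Absolute agreement, not consistency: a pure mean shift lowers it even at
  Pearson r = 1 (a property test).
* **Intra-device ICC**: the same estimator with the five repetitions as the
  rater dimension, per system.
* **CV%**: per subject `100 · sd / mean` over the five repetition values,
  averaged arithmetically across subjects (an aggregation the published
  tables leave unstated; the arithmetic mean is the simplest defensible
  choice). Zero-mean subjects are excluded with a warning count.

Participants are pooled within each limb separately, mirroring the per-limb
rows of published validation tables. Values are kept at full precision
everywhere; 2-decimal rounding happens only in `render_report()`.

# What the synthetic generator emulates

The default `sim_config()` encodes the emulated study: 11 participants × 2
limbs, 6 shoulder muscles (PM, AD, MD, PD, UT, LT), five task repetitions of
roughly 10 s at a self-selected pace separated by 5 s rests, EMG at
1000 Hz, IMU and camera at 100 Hz, cycle annotations derived from 30
frames/s video.

**EMG.** Each muscle's activation is a per-cycle Hann burst (smooth,
compactly supported, analytically tractable RMS) that amplitude-modulates a
zero-mean Gaussian wideband carrier — the standard phenomenological model of
surface EMG. Device and reference observe the *same* carrier; their burst
geometry mixes a participant-level shared latent with system-specific
variation according to a per-muscle `shared_fraction`. That fraction is the
generator's dial for muscle-dependent agreement: 1 collapses the systems
(identical signals up to offset), 0 decorrelates them, and the downstream
between-device correlation rises monotonically in between (a property
test). Defaults grade from 0.9 (AD) down to 0.5 (PD), emulating the
well-placed superficial muscles versus the anatomically awkward ones. Each
system then applies its own gain, baseline offset and white noise, and the
signal is digitized through the configured ADC transfer. The left
pectoralis major of both systems additionally receives a 72 beats/min
biphasic spike train (independent phases), the cardiac artifact that
plagues electrode sites near the heart; its amplitude is configurable and 0
disables it.

**Kinematics.** Ground truth is a segment orientation built from per-axis
quartic-sine bumps whose per-cycle peak-to-peak excursions equal the
configured ROM targets (defaults 30°/20°/45°), modulated by participant-
and cycle-level factors shared by both systems — same motion, two
observers. The camera sees the true orientation perturbed by small random
rotations (axis uniform, angle ~ N(0, 1°)); the IMU is rigidly mounted, so
it sees `R_true(t) R_mis` — a body-fixed misalignment, post-multiplied —
under the same rotation-noise model, reported as Euler angles. The
quartic-sine shape keeps the initial reference window at true rest;
otherwise cross-axis Euler leakage from a non-identity reference pose
contaminates noiseless ROM recovery at the half-degree level.
`imu_angle_gain` scales the excursion the IMU senses and is the honest way
to inject a known inter-device ROM bias (`delta = (gain - 1) ×` target);
no such injection exists for the EMG RMS because the per-cycle
normalization removes every affine degree of freedom — that invariance is
itself a tested property.

All randomness flows from one seed; cohort runs derive per-participant,
per-side, per-stage sub-seeds deterministically, so identical
(config, seed) pairs give bitwise-identical outputs.

**What it does not emulate.** Soft-tissue artifact dynamics, electrode
repositioning between sessions, inter-muscle crosstalk, marker occlusion
and labeling errors, Bluetooth packet loss, or drift in the IMU's sensor
fusion. Passing tests therefore demonstrate that the *pipeline* is correct
and calibrated under a faithful statistical model of the study — not that
any physical device meets the published agreement levels.

# Problem sizes used by the test suite

The stochastic checks run at sizes chosen to balance Monte-Carlo resolution
against a short default test run: alignment recovery over 500 seeded trials
(two-cycle recordings, random mounting rotations up to ±60° per Euler
angle, 1° orientation noise); ROM recovery over 200 seeded simulations of 2
participants × 2 limbs at the default protocol; limits-of-agreement
coverage over >1000 simulated pairs pooled from 8 cohorts with
statistically identical systems; the null-correlation check over 200 seeds
with fixed-duration cycles (random durations are shared by both systems
and alone induce a positive RMS correlation, so they are controlled out of
that check); and the ICC-versus-noise monotonicity over a 5-point
orientation-noise grid (0–8°) with common random numbers across grid
points.

# Known limitations

* ICC confidence intervals, hypothesis tests on bias, and proportional-bias
  regression are out of scope; the battery reports point estimates.
* Cycle segmentation is taken from annotations (the emulated study segments
  manually from video); there is no automatic cycle detection.
* The Euler-based ROM is convention-dependent near large excursions;
  excursions approaching 180° are rejected at generation time because
  unwrapping becomes ambiguous.
* `cv_percent` is undefined for zero-mean subjects and excludes them; with
  signed ROM differences this does not arise, but it can for arbitrary
  user-supplied tables.
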