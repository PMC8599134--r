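---
title: "Calibration-free gait analysis from foot-worn IMUs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibration-free gait analysis from foot-worn IMUs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imugait)
```

## The problem

Spatiotemporal gait parameters — stance and swing durations, the bilateral
stance sub-phases, cadence, stride length and walking speed — are routinely
measured on instrumented treadmills or walkways. Two inertial measurement
units (IMUs), one strapped to the instep of each foot, can measure the same
quantities anywhere, but most published pipelines require the sensor axes to
be aligned with anatomical axes of the foot, or a calibration session, or a
magnetometer. This package implements a pipeline that needs none of these:

* event detection operates exclusively on *norms, dot products and jerk
  norms* of the raw signals, all of which are invariant under any constant
  rotation of the sensor on the foot;
* detection thresholds are re-derived from each trial's own data, so one
  parameter set serves all walking speeds and gait styles;
* orientation for the stride integration is obtained by gyroscope strapdown
  with accelerometer-based inclination correction, which fixes the two tilt
  degrees of freedom — heading remains arbitrary and is irrelevant because
  only the *horizontal norm* of the per-stride displacement is reported.

Processing is deliberately acausal (whole recordings at a time): forward and
backward passes are used wherever they improve robustness.

## Event detection

**Foot-flat segmentation.** When the foot rests flat on the ground the
accelerometer norm is close to gravity and the gyroscope norm close to zero.
Two binary activity signals are computed — one from the deviation of the
accelerometer norm from 9.81 m/s², one from the gyroscope norm — each by
acausal hysteresis thresholding (band `(1±h)·th`, forward then backward
pass) followed by the removal of short phases: zero-phases shorter than
`t0_min` = 120 ms are removed first, then one-phases shorter than
`t1_min` = 180 ms. The two signals are OR-combined (motion if either channel
shows motion), short zero-phases are removed again and one-phases shorter
than `2·t1_min` are removed. Each 0→1 transition is a heel rise, each 1→0
transition a full contact, and the **rest instant** of a stride is the
midpoint of its foot-flat phase, rounded to the sample grid.

**Threshold adaptation.** Instead of fixed thresholds, each trial's
threshold starts at the mid-range of the signal and is iterated 200 times as
`th ← w·mean(x ≤ th) + (1−w)·mean(x > th)` with `w_a` = 0.85 for the
accelerometer and `w_ω` = 0.8 for the gyroscope. A lower bound
(`a_th_min` = 1.8 m/s², `ω_th_min` = 0) is applied after the iteration, not
inside it, since the bound is a safety floor rather than part of the fixed
point. For a constant signal the empty partition side contributes the
current threshold, the iteration is stationary, and the lower bound decides.

**Toe-off.** Between heel rise and the toes leaving the ground the foot
rotates one way; at toe-off the rotation reverses. The *tilt-rate* signal
projects the instantaneous angular rate onto the direction of the
accumulated rotation since heel rise — a mounting-invariant scalar whose
zero-crossing marks the reversal. To skip noise-crossings right after heel
rise and spurious maxima later in swing, the maximum over the first half of
the motion phase is located first, then the first sample at half that
maximum, then the first non-positive sample after it. A motion phase with no
such crossing yields an invalid stride (logged, excluded). A numerically
zero accumulated rotation (relative tolerance 1e−9) has no direction and
yields a zero tilt-rate.

**Initial contact.** Ground impact produces a sharp change of acceleration;
the jerk norm (backward difference of the accelerometer vector over one
sample interval; defined as 0 at the first sample) peaks at impact much more
distinctly than the acceleration norm itself. The search is restricted to a
window from `j_win·t_to + (1−j_win)·t_fc` to the full contact, and the first
sample whose jerk norm reaches `j_th` = 0.95 of the window maximum is the
initial contact.

**Stride assembly.** Stride *i* runs from its initial contact to the next
one; its heel rise and toe-off are those of the following motion phase. The
ordering `t_ic < t_fc ≤ t_rest ≤ t_hr < t_to < t_ic,next` is enforced;
violations invalidate the stride rather than stopping the analysis. Boundary
runs of the binary signals are exempt from short-phase pruning: recordings
begin and end mid-phase, so a truncated run carries no duration information.

## Bilateral phases

With both feet's event cycles on a common time base, each stride is split
into loading response (initial contact → contralateral toe-off), mid-stance
(→ ipsilateral heel rise), terminal stance (→ contralateral initial
contact), pre-swing (→ ipsilateral toe-off) and swing; single limb support
is mid-stance plus terminal stance. The transitions are implemented as
interval arithmetic on event times. Ties on the sample grid produce
zero-length phases, keeping the percentages summing to exactly 100. If the
required ordering (contra TO < ipsi HR < contra IC < ipsi TO) fails, the
stride is flagged *atypical* and only the phases delimited by contralateral
events (loading response, single limb support, pre-swing, swing) are
reported — the mid-/terminal-stance split is undefined in that case.
Support phases (double support, single support left/right, zero contact)
are labelled per sample from the contact intervals `[t_ic, t_to]` of both
feet; zero-contact phases are classified for completeness (running) but no
running-specific parameters are derived.

Only one foot instrumented? Stance, swing, cadence and the spatial
parameters are still computed — they need no contralateral events — and the
bilateral phases are omitted with a warning.

## Orientation estimation

The gyroscope turn-on bias is estimated as the mean angular rate over the
standing-rest segments at the beginning and end of the recording (at most
5 s each, identified by the foot-flat detector), subtracted from the whole
gyroscope sequence; estimates of 0.5 rad/s or more are rejected as
implausible. Bias-corrected rates are integrated by quaternion strapdown
(axis-angle increment per sample, renormalized every step so that round-off
cannot accumulate over long trials).

Strapdown alone drifts. The accelerometer supplies a vertical reference:
the measured acceleration is rotated into the (slowly drifting) strapdown
frame, where gravity dominates once motion accelerations are removed by a
moving-average filter of window `t_a` = 8 s run forward and then backward
(zero phase lag; the window shrinks at the sequence edges, which is benign
because trials begin and end at rest). The filtered acceleration, rotated
back to the sensor frame, is then used to build a correction quaternion
sequentially: at each sample the reference is rotated into the corrected
global frame, the axis `a_r × e_z` and angle `arccos` (argument clamped to
[−1, 1]) of its deviation from vertical are computed, and the *full* angle
is applied — no gain factor. Degenerate samples (axis norm below 1e−12,
including the antiparallel case, or a vanishing reference) leave the
correction unchanged. Because the correction axis is computed in the
inertial frame, the increment composes on the inertial side of the
correction quaternion; this makes each correction map the reference exactly
onto the vertical and keeps the estimator invariant to the sensor mounting,
which the random-rotation robustness check exercises directly. The final
orientation is the composition of correction and strapdown quaternions.

Applying the full correction every sample means the estimated inclination
follows the filtered gravity direction; the strapdown contributes the
dynamics between filter time scales. An 8 s window attenuates
stride-frequency content twice over by orders of magnitude, so the
correction does not chase per-stride motion.

## Stride integration

Accelerations are rotated into the inertial frame and, per stride, summed
from one rest instant to the next (zero-velocity anchors; the midpoint of
foot flat is used rather than the initial contact because the foot is
reliably still there). The printed summation convention includes the lower
bound, so the velocity at the first rest instant equals one sample's
increment; the effect (< `T_s`·‖a‖) is far below reporting precision.
Residual velocity at the closing rest instant — from accelerometer bias and
orientation error — is removed by subtracting a linear ramp, which makes the
corrected velocity exactly zero at both anchors and cancels any *constant*
acceleration error exactly (a constant bias leaves only the second-order
residual `b·T_s·T/2`, fractions of a millimetre). The corrected velocity is
summed again into a position trajectory; stride length is the horizontal
norm of the displacement, walking speed is stride length over the
initial-contact-to-initial-contact stride time, cadence is `120/T_stride`
steps per minute. Strides adjacent to invalid events yield no spatial
parameters.

## Trial summary

Per-foot parameters are averaged after dropping the first and last 3 valid
strides (gait is not steady when starting and stopping); if too few strides
remain, all are used and a warning is recorded. The combined summary pools
the retained strides of both feet rather than averaging the two per-foot
means, matching the per-stride granularity of the reporting. A comparison
utility computes, per parameter, the mean absolute difference and the mean ±
standard deviation (n−1 normalization) of signed differences against a
reference table — the agreement statistics used when validating against an
instrumented treadmill.

## The synthetic gait generator

Real validation data for this kind of pipeline comes from instrumented
treadmills and is rarely shareable, so the package ships a two-foot gait
simulator with exact ground truth. Each cycle consists of four
piecewise-smooth segments (heel-rise rotation about a toe pivot with a
quintic-smoothstep pitch ramp; swing with a quintic forward profile, a
smooth vertical arc and the pitch returning to zero; a landing with an
attack-decay impact deceleration plus a quarter-cosine braking profile and a
1.5 cm vertical heel settle; and a constant foot-flat pose). Velocity is
continuous across all transitions; the only deliberate transient is the
acceleration step at initial contact, whose discrete jerk the
initial-contact detector relies on. The pitch ramp guarantees exactly one
tilt-rate sign change per cycle, located at toe-off.

The gyroscope channel is synthesized from quaternion increments and the
accelerometer channel from velocity increments (interval-averaged specific
force), the behaviour of an internally integrating, decimating sensor. This
makes the noise-free channels *exactly* invertible by the pipeline's own
integration schemes: strapdown reproduces the true orientation to machine
precision and right-Riemann velocity integration reproduces the true
velocity, so ground-truth comparisons measure algorithmic error, not
synthesis error. The sensor error model applies an arbitrary constant
mounting rotation to both channels (random by default), a turn-on bias
drawn from U(−0.01, 0.01) rad/s per gyroscope axis, and white Gaussian
noise (defaults 0.01 rad/s and 0.1 m/s² per axis, typical consumer-MEMS
figures).

Default study conditions: 3 km/h, cadence 110 steps/min (stride time
120/110 s, stride length speed × stride time ≈ 0.909 m), stance 60 % per
foot, contralateral shift 50 %, 120 s duration with 5 s of standing before
and after (these margins also feed the bias estimator). Within a cycle
starting at heel rise, the heel-rise segment lasts one third of stance, the
loading phase one fifth of stance, and foot flat the remainder — at 60 %
stance this puts full contact at 12 % and heel rise at 40 % of the cycle,
textbook values. The simulator models overground walking, where the
zero-velocity assumption holds exactly during foot flat; treadmill belt
kinematics (foot at belt speed during stance) are out of scope. Passing
tests on this generator demonstrate correct implementation of the
algorithms under their stated assumptions — not performance on real
pathological gait, soft-tissue artefacts, or turning.

## Numerical choices and degenerate inputs

* Event times are kept on the sample grid; derived instants (rest instant,
  window starts) are rounded to the nearest sample.
* Quaternions are renormalized every strapdown and correction step; unit
  norm is maintained to 1e−9 over arbitrary trial lengths.
* `arccos` arguments are clamped; zero-norm rotation axes skip the
  correction step; a zero-norm angular rate produces an identity strapdown
  increment.
* Ties in window maxima resolve to the earliest sample.
* A constant signal in the threshold adaptation returns the constant, then
  the lower bound applies.
* Standing-only recordings raise an "insufficient strides" error; recordings
  with fewer than two complete motion phases likewise.
* The sampling-interval check on CSV input tolerates 1 % relative jitter and
  takes the median time difference as `T_s`.

## Validation strategy

The test-suite oracles are independent re-implementations (brute-force
run-length processing for hysteresis and pruning, direct re-iteration for
the threshold fixed point, a 100× finer integration for strapdown) and the
simulator's exact ground truth for the end-to-end properties: event timing
to within a few samples, stance/stride-length/speed/cadence recovery, exact
mounting-rotation invariance of all event times, and the structural
identities (stance + swing = 100 %, phase decomposition sums to 100 %,
drift-corrected velocity exactly zero at rest anchors). End-to-end checks
use 30 s trials; the acceptance checks use the full 120 s study conditions
and 20 noise seeds, sizes chosen to exercise ~100 strides per trial while
keeping the suite quick to run.
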