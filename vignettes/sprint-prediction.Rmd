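---
title: "Predicting sprint propulsion and performance from wheelchair set-up"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting sprint propulsion and performance from wheelchair set-up}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheelsprint)
```

## The problem

Sports wheelchairs are configured per athlete, and small changes to seat
height, seat depth, seat angle or tire pressure measurably change sprint
performance. On-court optimization is expensive: each candidate set-up needs
chair adjustment, familiarization and repeated timed sprints. `wheelsprint`
implements a two-step model-based shortcut for 5 m sprints from standstill
in wheelchair rugby: a calibrated planar linkage model predicts how
propulsion kinematics change with set-up, and a per-athlete
partial-least-squares (PLS) regression maps set-up plus kinematics to sprint
time, so that untested set-ups can be screened before going back on court.

## The linkage model

All geometry lives in the sagittal plane, in a frame with the origin at the
rear-wheel axle, x forward and y up. The hip is assumed coincident with the
rear corner of the seat, so it sits at `(-seat_depth, +seat_height)` and
moves with the seat. Three rigid segments hang off it: trunk (hip to
acromion), upper arm, forearm. Trunk flexion is a positive angle from
vertical; the upper arm is anti-parallel to the trunk; the forearm
orientation encodes the contact assumption:

* **original** — forearm perpendicular to the wheel tangent at contact:
  orientation `-theta_TI` from vertical;
* **altered** — forearm approximately parallel to the tangent (athletes with
  trunk function who contact in a flexed position): orientation
  `90 - theta_TI`, i.e. a 90-degree shift of the forearm term.

The predicted hand angle is the principal-value arctangent of
`hand_x / hand_y` — the direction of the modelled hand from the axle,
measured from top dead center (TDC), in front positive — scaled by a
dimensionless per-stroke coefficient `beta`. Release always uses the
parallel-forearm geometry evaluated at the most-flexed (release) trunk
angle. `beta = 1` means the geometric assumption holds exactly; the
calibrated value absorbs individual technique, hand landmarks and residual
model error.

Assumptions worth stating plainly:

* The model predicts a hand *direction*, not an intersection with the
  push-rim: wheel radius never enters, and there is no wrist/hand segment,
  no 3-D motion and no force or torque estimation.
* Seat angle has no direct geometric role. It acts only through the
  athlete's trunk-angle profile: contact/release trunk angles are measured
  at the three tested seat-angle levels and interpolated linearly in
  between (constant beyond the profiled range). This mirrors the empirical
  link between seat inclination and trunk motion rather than asserting a
  mechanical one.
* The arctangent is the principal value with `hand_y > 0` enforced as a
  precondition; a hand at or below axle height is a degenerate geometry and
  raises an error naming the offending set-up rather than silently wrapping
  quadrants.
* The exact perpendicular-forearm formula of the antecedent daily-propulsion
  model is not uniquely determined by its published description; this
  package reconstructs it as the parallel-forearm equation minus the
  90-degree addition (`phi = -theta_TI`). Since predictions are linear in
  `beta`, any fixed alternative forearm orientation mostly rescales the
  calibrated coefficient, so this choice affects coefficients, not fitted
  angles.
* Trunk angular velocity is assumed constant across the stroke in the
  conceptual model but has no downstream use in the printed equations; it is
  not implemented.
* All angles are degrees end-to-end; lengths mm; pressure psi; time s.

## Coefficient calibration

`fit_coefficient()` minimizes the absolute error between a measured angle
and `beta * base_angle` over the grid -0.5 to 1.5 in steps of 0.01 (the
prediction is linear in `beta`, so the geometry is evaluated once at
`beta = 1`). Ties break toward the smaller coefficient and results are
confined to the grid. `calibrate_athlete()` applies this per stroke and per
set-up, pooling left/right sides (per-side means first, then the mean of
side means, which also averages repeat trials — whether the original
protocol averaged trials before fitting is not documented; averaging is the
package's choice and reduces the influence of single-trial outliers), then
averages the per-set-up fits across set-ups and rounds to two decimals. The
frozen per-stroke coefficients encode the assumption that an athlete keeps
one propulsion technique across set-ups; `corrupt_relationship()` exists
precisely to probe what happens when that assumption fails.

A practical identifiability note: the same coefficient error costs more
degrees where the base angle is larger, which is why release-angle
predictions (larger magnitudes, later strokes) degrade faster than contact
predictions — the package's tests assert this monotonicity directly.

## The test design

`l9_array()` returns the canonical L9(3^4) orthogonal array (GF(3)
Latin-square construction) with the all-current row first, so the first
realized set-up always replicates the athlete's own configuration. Levels
are current / +delta / -delta with default deltas of 15 mm (seat height,
seat depth), 5 degrees (seat angle) and 15 psi (tire pressure). The array
itself is fixed; randomized testing order is a separate seeded shuffle
(`randomize_run_order()`) that never permutes `setup_id`.
`level_average_analysis()` compares per-level response means against the
grand mean; on the balanced L9 the three effects of each parameter sum to
zero and main effects of an additive response are recovered exactly.

## The PLS performance model

Thirteen predictors — seat height, seat depth, seat angle, tire pressure,
and contact, release and push angles for strokes 1–3 — predict sprint time.
`train_pls()` is a NIPALS PLS1: components maximize predictor–response
covariance, with mean-centering of both sides. Centering-only is the
default, matching the conventional behaviour of the reference PLS routine
this pipeline emulates; unit-variance scaling is available via `scale =
TRUE` and predictions are then invariant to predictor units. Per-component
explained variance in the response drives `select_components()`: components
are accepted until one contributes less than the plateau threshold (2
percentage points by default, a number the original description leaves as
"appeared to plateau") and at most five are used.

Training rows are per-trial (two sprints per set-up) rather than per-set-up
means — with 13 predictors and seven training set-ups the extra rows are
worth more than the noise averaging. The split is always by set-up: the
first seven of the nine set-ups train, the final two are held out, and
held-out predictions use the linkage model's *predicted* kinematics, never
the measured ones, so the evaluation chains both modelling steps. Models
are strictly per-athlete; no pooling across athletes is attempted.

## Evaluation statistics

Differences are always `predicted - measured` (positive = over-prediction),
summarized by mean, sample (n-1) SD, min, max. Per-stroke error
distributions (one mean difference per athlete) are compared between the
three stroke pairs, separately for contact and release, with two-sided
Welch t-tests at a Bonferroni-adjusted alpha of 0.05/6 (reported as 0.008).
Sidedness and the n-1 SD are package choices where the protocol is silent.

## The synthetic cohort generator

`generate_cohort()` emulates the structure of an elite squad study: by
default 8 athletes (3 using the altered contact method, 5 the original),
each tested in their own realized L9 design with 2 sprints per set-up and
the first 3 strokes measured bilaterally. Per athlete it samples segment
lengths (trunk 400–550, upper arm 280–340, forearm 240–300 mm), a baseline
set-up (seat height 350–450 mm, seat depth 100–150 mm, seat angle 5–20
degrees, pressure 90–120 psi — typical rugby-chair ranges), a trunk profile
(contact trunk angles 5–30 degrees with an athlete-specific response of
posture to seat-angle level; release angles 20–45 degrees more flexed), and
true per-stroke coefficients drawn on the two-decimal grid in [0.8, 1.2] so
that the calibration fixed point is exactly attainable. Noiseless angles
come *through the linkage model*; measurement noise is additive Gaussian
(default SD 2 degrees, the order of magnitude implied by reported
technical-error-of-measurement percentages). Sprint time is linear in the 13
z-scored noiseless predictors with weights in [-0.05, 0.05] and intercept
2.0–2.8 s, plus Gaussian trial noise (default SD 0.05 s) — by construction
the structure PLS can represent, so that pipeline failures are
attributable, not baked in. All randomness flows from one seed.

What the generator does *not* emulate, and hence what green tests do not
show about real data: release angles have the model's own modest magnitudes
(roughly 10–30 degrees) rather than the 70–105 degrees seen on court —
the planar direction-only geometry cannot reach those values with bounded
coefficients, which is exactly why calibrated-coefficient release
predictions are fragile in practice; measured angles are conditionally
independent Gaussian rather than autocorrelated within a sprint; athletes
never fatigue or learn; and the set-up-to-time relationship is exactly
linear unless deliberately broken. `corrupt_relationship()` introduces the
one nonlinearity the study design cares about — a set-up-dependent
perturbation of the true coefficients of the two held-out set-ups,
re-using the original noise draws so comparisons are exactly paired — and
the pipeline's held-out error provably grows with it.

## Numerical choices and degenerate inputs

* Trigonometry in degrees via `sinpi`/`cospi`, so right angles are exact.
* Trunk-profile interpolation: linear between the three profiled levels,
  constant extrapolation outside; evaluation exactly at a knot equals the
  direct table value.
* Grid fitting returns the first (smallest) minimizer, making tie-breaks
  deterministic; an exactly-zero base angle with a nonzero measurement is
  an unidentifiable-coefficient error, not a clipped value.
* NIPALS stops early (with the component count truncated) if the residual
  predictor matrix becomes uninformative; constant responses, identical
  training rows, and dimension mismatches are errors.
* The noiseless end-to-end closure check trains on the full design at full
  rank and asserts reproduction of all generated times to 1e-6 s. With only
  the seven training set-ups, held-out feature rows leave the affine span
  of the 14 training rows (the kinematic features are mildly nonlinear in
  the set-up parameters), so machine-precision closure on held-out rows is
  not a property even of noiseless data; the honest 7/2 split is asserted
  under the noisy regime instead, where the pipeline's held-out mean
  absolute error stays under 0.1 s at the default noise levels.
* Coefficient-recovery tolerance (0.05 at 2-degree noise) is asserted on
  the cohort mean absolute error: per-stroke recovery precision scales with
  the base-angle magnitude, and original-method contact geometries can have
  base angles under 10 degrees where a single set-up's fit is noisy even
  though the nine-set-up average is well-behaved.

## Problem sizes used by the test-suite

The suites run cohorts of 1–8 athletes (the full 8 wherever a study-sized
structure matters), 1000 random geometries against the segment-placement
oracle, 200 random grid fits against exhaustive search, and 10,000
replicates for the null-uniformity check of the Welch test — sizes chosen
so the whole suite exercises every advertised property in well under a
minute of compute.

## Known limitations

Everything is sagittal-plane and direction-only; no rim contact, forces, or
3-D kinematics. Seat angle acts purely through measured trunk profiles.
Frozen per-athlete coefficients cannot represent set-up-specific technique
adaptation (the drift generator quantifies the cost of that assumption but
the pipeline cannot correct it). PLS models are per-athlete with 14
training rows — appropriate for screening set-ups, not for inference about
predictor importance — and no uncertainty quantification is attached to
predictions.
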