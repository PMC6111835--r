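---
title: "Methods: exercise evaluation from skeletal joint streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exercise evaluation from skeletal joint streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rehabmotion)
```

## The measurement model

The input is a skeletal motion stream: for each frame, up to 25 named
joints with a 3D position in meters (camera space: `y` vertical, `z`
along the sensor–subject axis, `x` transverse) and a tracking state.
The reference deployment places the sensor 1.2 m above the floor with
the subject standing 2.5 m away, facing it; nothing in the analysis
depends on those numbers beyond the synthetic generator using them for
its base pose.

Frame validation is the only preprocessing: a frame is discarded when no
body was detected or when a joint of interest is flagged `NotTracked`.
`Inferred` joints are kept — the sensor's own estimate under partial
occlusion is usually serviceable, and the detectors' hysteresis absorbs
the extra noise. There is deliberately **no smoothing, resampling or
outlier rejection** anywhere in the pipeline: robustness is the
detectors' job, and unfiltered series keep the recorded angle history
clinically interpretable.

## Joint angles

At an apex joint, the two adjacent segments define vectors
$\vec u$ (proximal → apex) and $\vec v$ (apex → distal), and

$$\alpha = \frac{180}{\pi}\,\operatorname{atan2}\!\left(\lVert\vec u \times \vec v\rVert,\; \vec u \cdot \vec v\right).$$

A plain arctangent of the ratio would be undefined when
$\vec u \cdot \vec v = 0$ and negative for obtuse configurations; the
two-argument form agrees with it on acute angles and extends it
continuously to $[0^\circ, 180^\circ]$, which is the intended geometric
quantity. With this orientation the series reports the **deviation**
angle: 0° for a straight limb. The anatomical interior angle is
$180^\circ - \alpha$; which scale a detector's thresholds live on is an
explicit configuration field, never hard-coded.

## Center of mass

The body is modeled as $N = 16$ rigid segments. Each carries a fixed
fraction of total body mass from a standard male anthropometric table
(Head 8.26, Thorax 20.10, Abdomen 13.06, Pelvis 13.66; per side Upper
Arm 3.25, Forearm 1.87, Hand 0.65, Thigh 10.50, Leg 4.75, Foot 1.43 —
percent), applied to all subjects. Segment mass is concentrated at the
midpoint of its two endpoint joints, and

$$\mathrm{bCOM} = \frac{\sum_i M_i\,\mathrm{sCOM}_i}{\sum_i M_i},
\qquad M_i = \mathrm{fraction}_i \cdot M.$$

Two modeling choices are ours and documented as such:

* **Endpoint mapping.** Anthropometric tables name anatomical segments,
  not sensor joints. We span each segment with the nearest joints
  (Head = Head–Neck, Thorax = Neck–SpineMid, Abdomen =
  SpineMid–SpineBase, Pelvis = HipLeft–HipRight, then
  Shoulder–Elbow–Wrist–HandTip and Hip–Knee–Ankle–Foot chains). The
  mapping is data in the segment table and can be overridden.
* **Normalization.** The printed fractions sum to 99.98%, not 100%. We
  normalize by $\sum_i M_i$, which redistributes the 0.02% deficit
  proportionally; the alternative (divide by $M$) would bias every COM
  toward the origin by a factor of 0.9998. The choice is invisible at
  sensor noise levels but the normalized form is exactly
  translation-equivariant, which the tests rely on.

## Repetition counting

`count_flexions()` is a two-state hysteresis automaton. Starting
*extended*, it switches to *flexed* when the angle crosses the
flexed-side threshold, and counts one repetition (returning to
*extended*) when the angle subsequently crosses the extended-side
threshold. Samples between the thresholds change nothing, so noise
below the gap cannot create or destroy counts; comparisons are
inclusive on both sides so a trace resting exactly on a threshold
cannot oscillate the automaton.

Defaults follow clinical practice for arthropathic joints: elbow
(50°, 100°) on the interior angle — flexed once the elbow closes to
≤ 50°, extension complete at ≥ 100° — and knee (70°, 30°) on the
deviation angle. Read on its own scale, each pair forms a consistent
hysteresis band (the flexed-side threshold on the flexed side of the
extended-side one); the constructor enforces that ordering for custom
bands too. The thresholds are intentionally submaximal so that patients
with restricted range of motion can complete repetitions, while still
being far from the angles seen in normal walking (false-positive
control).

## Step climbs

Ankle-angle-based exercise detection is unreliable with depth cameras —
foot and ankle joints are the noisiest. The step detector therefore
uses two conditions that must overlap in time:

1. **Body rise.** The hip center (SpineBase) exceeds its standing
   baseline by `hip_rise_threshold` (default 0.09 m ≈ 60% of a 0.15 m
   step block). The baseline is the mean hip height over the first 2 s
   and is re-anchored over the 2 s following each completed descent, so
   slow postural drift cannot accumulate; the next rise is searched
   only after the re-anchoring window.
2. **Knee cycle.** The stepping knee completes a flexion–extension
   cycle under the same hysteresis semantics (70°/30° deviation).

A climb is credited to a foot when a raised-hip interval overlaps a
knee cycle on that side (at most one climb per interval per foot); the
descent is counted when the hip returns within half the rise threshold
of baseline, and is credited to the same foot. Descents therefore never
exceed climbs, and a hip rise with straight knees (tip-toe) or knee
cycles without body rise count nothing. A descent needs no knee-cycle
check of its own: stepping down backwards off a block flexes the knee
much less than the climb, and the hip return is unambiguous once a
climb has been counted. The ankle angle history is recorded throughout
for clinical review but never consulted.

## Balance

The subject leans to move the COM toward eight compass targets in
clockwise order N, NE, …, NW, where N is the front-facing direction
(toward the sensor, $-z$) and E the subject's right ($+x$). Targets sit
at `excursion` meters from the calibrated start position `idlePos`
(mean COM over the first 2 s) in the floor-parallel XZ plane; each
direction grants `time_per_target` = 10 s and scores

$$\mathrm{score}_d = 100\cdot\frac{\text{time on target}_d}{\text{time allowed per target}}.$$

On-target time integrates actual timestamp differences, so dropped
frames degrade the estimate gracefully rather than corrupting it. The
window for direction $d{+}1$ opens at the timestamp of the frame
*after* the COM first returns within `idle_radius` of `idlePos`; this
off-by-one convention means the return frame itself (necessarily off
target) is not charged against the next window, so a subject who is on
target for a window's full duration scores exactly 100.

Difficulty levels raise the excursion: 4 / 6 / 8 cm for levels 1–3.
The levels were set empirically in clinical use and no canonical values
exist, so ours are calibrated to the same intent — a mild sway reaches
level 1, level 3 demands near-maximal reach — and are configuration,
not constants. Likewise the return-to-start tolerance reuses the 1.5 cm
target radius (symmetric treatment of idle and target spots). If a
stream ends mid-protocol, completed directions keep their scores and
the remainder is flagged incomplete rather than scored 0.

## The synthetic generator

`gen_flexion_session()`, `gen_step_session()` and
`gen_balance_session()` emulate the sensor: a base standing pose with
proportions linear in height (hip center near 1.0 m for a 1.72 m
adult), exercise trajectories realized **geometrically** — distal
segments rigidly rotated about the apex joint for flexions, whole-body
translation for step rise and balance lean — so detectors only ever see
joint positions. Angle noise perturbs the planned rotation per frame
before the geometry is built; position noise is additive isotropic
Gaussian jitter after synthesis; dropouts flag joints `NotTracked`
without touching the stored position, mirroring how validation (not the
value) removes them. Identical plans and seeds give bit-identical
streams, and the caller's RNG state is left untouched.

Defaults encode the study conditions the package is validated under:
30 Hz sampling, 5 repetitions per series at 12 repetitions/min, squat
amplitude 85° deviation, elbow amplitude 150° deviation (a 30° interior
angle), 0.15 m step blocks at a 6 s cadence, subject height 1.72 m and
mass 67 kg (the control cohort means). The generator is the acceptance
oracle precisely because the original human recordings are not
available; its ground truth is exact by construction at zero noise and
dropout, which is how the oracle-equivalence suites use it.

What the generator does **not** emulate — and what passing tests
therefore cannot show — includes: occlusion-correlated errors (real
ankle noise is structured, not isotropic), inter-joint noise
correlation, soft-tissue and clothing artifacts, reaction-time and
learning effects in balance, and any biomechanically realistic
dynamics. Trajectories are kinematic stand-ins. Results on real
recordings will be worse than on synthetic ones; the suites establish
correctness of the algorithms, not field accuracy of the sensor.

## Numerical choices

* Angle computation is exact at 0°, 90° and 180° via `atan2`; zero-length
  segment vectors raise an error rather than returning NaN.
* Threshold crossings are inclusive (≥ flexed-side, ≤ extended-side).
* Balance on-target time for the frame straddling a window's end is
  clipped at the window boundary.
* Canonical CSV output prints 17 significant digits, so write→read
  round-trips positions bit-identically.
* Achievement display values round half away from zero to integer
  percent, matching clinical summary tables; exact means and standard
  deviations are kept alongside. Of the published per-subject tables
  shipped in `inst/extdata`, three mean cells (controls left step,
  patients left knee, patients left step) print values that differ from
  the arithmetic mean of their column by up to 0.6 points under any
  standard rounding rule; the package reproduces the remaining cells
  exactly and makes no claim about those three.

## Problem sizes in the validation suites

The oracle-equivalence suites run 210 randomized plans (120 flexion
with 0–10 repetitions, 50 step with 0–6 climbs, 40 balance with uniform
random per-direction compliance at random levels) at zero noise, plus
25 knee sessions at 2° angle noise — comfortably inside the 70/30
hysteresis quarter-gap bound of 10°. Balance quantization is checked at
30 Hz against planted compliance fractions {0, 0.25, 0.5, 0.73, 1},
where one frame interval bounds the score error at 100/300 ≈ 0.34
points. These sizes give every detector hundreds of planted events
while the whole suite stays fast enough to run on every change.

## Known limitations

* The male mass table is applied to all subjects; female and pediatric
  tables differ by 1–2 points per segment.
* The COM is a midpoint model: real segment COMs sit 40–60% along the
  segment, not at 50%. For *displacement*-based balance scoring the
  bias largely cancels, which is why the simpler model is acceptable
  here.
* Multi-body streams are parsed and split, but each body is analyzed
  independently; there is no interaction analysis.
* Step descent counting assumes the subject steps down to the original
  floor level; stepping off to a different elevation would defeat the
  baseline re-anchoring.
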