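# rehabmotion

Exercise analysis for skeleton-tracking rehabilitation sessions.

Patients with joint disease — the motivating case is hemophilic
arthropathy, where recurrent joint bleeds limit range of motion — are
prescribed supervised exercise routines: elbow and knee
flexion/extension, step climbs, and multi-directional balance training.
Consumer depth cameras (Kinect V2 class) track a 25-joint skeleton at
~30 Hz, which makes it possible to count repetitions and score balance
automatically and report progress to the clinician remotely.
`rehabmotion` is a hardware-independent implementation of that analysis:
it consumes timestamped 3D joint positions (meters, camera space, with a
per-joint tracking state) from any source, and ships a deterministic
synthetic motion generator that stands in for the sensor, so every
detector is validated against sessions whose correct answer is known by
construction.

## What it computes

**Joint angles.** For an apex joint with adjacent segment vectors
**u** (proximal→apex) and **v** (apex→distal),

    α = (180/π) · atan2(|u × v|, u · v)

the geometric angle in [0°, 180°]. Series report the *deviation* angle
(0° = straight limb); detectors that need the anatomical interior angle
use 180° − α. Frames with no body or with a required joint flagged
`NotTracked` are discarded, never interpolated; there is no filtering.

**Center of mass.** The body is 16 rigid segments with male
anthropometric mass fractions (Head 8.26%, Thorax 20.10%, …, summing to
99.98%). Each segment's mass sits at its midpoint
`sCOM = s1 + (s2 − s1)/2`, and the body COM is the mass-weighted mean
`bCOM = Σ Mᵢ·sCOMᵢ / Σ Mᵢ`.

**Repetition counting.** A two-threshold hysteresis automaton: a
repetition is counted only after the angle crosses the flexed-side
threshold *and then* the extended-side threshold (elbow: interior
50°/100°; knee: deviation 70°/30°). Noise smaller than the hysteresis
gap cannot double-count.

**Step climbs.** A climb on foot F requires, overlapping in time, (a)
the hip center rising ≥ 0.09 m above its standing baseline and (b) a
knee-F flexion–extension cycle. The ankle angle is recorded for clinical
review but deliberately never used for detection.

**Balance.** Eight compass targets (N, NE, …, NW; N = toward the
sensor) at a level-dependent excursion from the calibrated start
position; each direction grants 10 s and scores
`100 · time-on-target / 10 s`, with a return to start required between
directions.

**Reporting.** Per-series achievement rate
`min(100, 100·detected/prescribed)`, aggregated as mean ± sd over series;
JSON + text + plot report bundles.

## Worked example

```r
library(rehabmotion)

# a synthetic squat session: 5 repetitions, 2° angle jitter, 3 mm position noise
plan <- motion_plan("squat", repetitions = 5, noise_angle = 2,
                    noise_pos = 0.003, seed = 42)
sess <- gen_flexion_session(plan)
res  <- count_flexions_stream(sess$stream, flexion_config("knee", "right"))
res
#> <flexion_result> knee (right): 5 repetition(s), 811 samples
head(res$events, 3)
#>   t_flexed t_extended
#> 1  2.50000   5.433333
#> 2  7.50000  10.400000
#> 3 12.53333  15.500000
achievement_rate(res$flex_count, 5)
#> [1] 100
```

The automaton found all five planted repetitions; each event row
brackets one repetition (time the knee crossed 70° of flexion, time it
re-extended past 30°), and detecting 5 of 5 prescribed repetitions is a
100% achievement rate. A balance session scores each direction as the
percentage of its 10 s window spent on target:

```r
b  <- gen_balance_session(motion_plan("balance",
        compliance = c(1, .8, .6, .9, .4, .7, 1, .5), seed = 42))
rb <- score_balance(b$stream, b$cfg, mass_kg = 67)
rb
#> <balance_result> level 1 scores (%):
#>   N  NE   E  SE   S  SW   W  NW
#> 100  80  60  90  40  70 100  50
```

A command-line interface wraps the same functions
(`inst/cli/rehabmotion`): `simulate` writes a canonical CSV stream plus
a ground-truth sidecar, `analyze` produces a report bundle, `summarize`
aggregates achievement over sessions.

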