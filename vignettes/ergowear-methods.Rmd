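---
title: "Methods: posture scoring, kinematic wear, and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: posture scoring, kinematic wear, and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ergowear)
```

## The problem

Work-related musculoskeletal disorders are driven by sustained and repeated
awkward postures. Wearable inertial motion capture yields joint-angle time
series (here 20 Hz) over a work shift; the analysis task is to turn those
angles into (a) an instantaneous ergonomic risk per sample, (b) a cumulative
per-joint-motion hazard that remembers how long risky angles were held, and
(c) a shift-level report that attributes risk to the posture classes that
generated it. `ergowear` implements exactly that scoring core; it does not
ingest raw IMU signals, train posture recognisers, or parse proprietary
motion-capture formats.

## Finite-state scoring

### LUBA

Each of nine upper-body joint motions has a fixed partition of the angle
axis into intervals carrying integer discomfort scores. The transcription
convention is: intervals are lower-exclusive/upper-inclusive exactly as the
printed thresholds read, so a back flexion of exactly 30° scores 1 and
30.0001° scores 3. Lateral bending and axial rotation are stored signed but
scored on magnitude — bending 25° left or right is equally bad. Because the
intervals tile the real line, scoring is total and unambiguous; the test
suite checks tiling and uniqueness against an independent predicate
transcription of every row, on a dense grid plus boundary neighbourhoods.

The global score `G` sums, over the back and *one* arm, every score strictly
above the minimum of 1. The arm is chosen per sample as the one with the
higher shoulder+elbow score sum (`arm_selection = "worst_sum"`); the tie
goes to the right arm, an arbitrary but deterministic choice the source
method leaves open. Summing only above-minimum scores makes `G = 0`
equivalent to "every contributing motion neutral", and the attainable range
is 0–62 (the maxima 15 + 13 + 10 + 11 + 8 + 5 over back and one arm).
Categories I–IV apply at G ≤ 5, ≤ 10, ≤ 15, > 15. Whether the category
boundaries presuppose the zero-floored G is not specified anywhere we could
find; we apply them to G as defined above.

### AULA / ALLA / AWBA

The whole-body method works on sagittal flexion/extension only, in risk
levels 1–4. Two deliberate transcription choices:

- The upper-limb table assigns level 2 to back flexion beyond 72.5°
  *regardless of the arms*. This is counter-intuitive (deeper back flexion
  can lower the level) but is implemented as printed; the tests pin it.
- A printed "72,5" threshold is read as the typographic 72.5.

Which arm "the shoulder" means is unstated; we evaluate both arms and keep
the worse AULA level (conservative). Likewise the lower-limb rule uses the
more-flexed knee. Kneeling is its own lower-limb state, pinned at level 3
whatever the knee angle — so the posture label is a genuine input to AWBA,
not just report metadata. Level 1 is reserved for sitting and is
deliberately unreachable here. All postures other than kneeling route
through the knee-angle branch, including carrying/walking, which therefore
oscillates between levels as gait flexes the knees — a known behaviour of
the method on dynamic tasks, not a bug.

## The kinematic wear index

Per joint motion, a dimensionless accumulator `V ∈ [0, 1]` with
charge/discharge dynamics inspired by the RC-circuit behaviour of muscle
fatigue. While the motion's LUBA score `S` exceeds its minimum (wear phase):

$$V(t) = 1 - (1 - V(t_0))\, e^{-\int S\,d\tau / C}$$

and while at the minimum (recovery):

$$V(t) = V(t_0)\, e^{-r t / C}.$$

Calibration fixes the two constants per motion from two interpretable
parameters: `v_max = 0.993` (five time constants — "fully charged") and
`t_max = 240` s (onset of discomfort for a static low-force posture):

$$C = \frac{-S_{avg}\,T_{max}}{\ln(1 - V_{max})}, \qquad
  r = \frac{-C}{T_{max}} \ln\!\frac{1 - V_{max}}{V_{max}},$$

with `S_avg` the midpoint `(1 + max)/2` of the motion's score scale (8 for
the back's 1–15 flexion scale, 3 for the elbow's 1–5). Capacity is linear in
`S_avg`, so motions with wider scales wear proportionally slower per score
point — the mid-scale posture always takes the same 240 s to saturate.

**Numerical scheme.** Scores are piecewise constant within a sample, so the
per-sample update
`V' = 1 − (1 − V)·exp(−S·dt/C)` (wear) / `V' = V·exp(−r·dt/C)` (recovery)
is the *exact* solution of the continuous model on each sample — not an
Euler step. Consequences the tests verify: exponents add across samples
(closed-form agreement on any constant-score segment, and agreement to
1e-4 with an independent fine-step ODE integrator); both 0 and 1 are fixed
points, so boundedness needs no clipping in exact arithmetic (a `pmin/pmax`
guards rounding only); charging from 0 under `S_avg` reaches exactly 0.993
at exactly 240 s, and discharging from 0.993 reaches 0.007 after 240 s.

**Phase semantics.** Recovery is triggered per motion, by that motion's own
score being minimal; each of the nine LUBA motions wears and recovers
independently (knees carry no wear — LUBA has no knee scale). One passage of
the source material instead suggests recovery only when the *global* score
is minimal; we regard the per-motion reading as the operative definition
(it matches the per-motion equations), and expose the global trigger as the
unendorsed experimental option `run_config(recovery_trigger = "global")`,
under which a motion at its own minimum *holds* while any other motion is
loaded.

**Threshold statistics** count samples strictly above the threshold
(default 0.7, from a muscle-fatigue model; configurable because its
suitability for short trials is doubtful — a 2-minute trial can breach it,
which says more about the threshold than the worker). No interpolation:
time above = sample count × dt.

## Posture labels

Posture recognition natively emits one of eight classes per non-overlapping
1-s window; ergonomic metrics are per sample. `broadcast_windows()` repeats
each window label `sample_rate` times. Trailing samples past the last full
window (at most one window's worth) are labelled `others` and flagged
`partial`, and excluded from per-posture aggregates — a conservative edge
rule, since nothing in the source fixes the alignment at trial edges. A
full unlabelled window is treated as a coverage error, not padded.

Any function mapping a 1-s window slice to a class can be registered as a
classifier plug-in; the deep-learning recogniser the framework was designed
around is one such plug-in and is out of scope (its weights require a
proprietary dataset). The shipped `heuristic_classify()` is a deterministic
rule set over window-mean back/knee/shoulder angles and within-window knee
variability whose thresholds sit halfway between the synthetic templates.
It exists so synthetic pipelines run end to end; its ≥ 0.9 agreement on
synthetic trials is a self-consistency property of the fixture design and
claims nothing about real recordings.

## Reports

`build_report()` computes, per posture class, the fraction of labelled time
and the arithmetic mean of the per-sample risk (global LUBA score, or AWBA
level) over that class's samples; wear trajectories are summarised by time
above threshold, with the up-to-three longest-breaching motions listed. It
is a pure function: identical inputs give byte-identical JSON.

`merge_reports()` aggregates trials by *mean of per-trial values*, not by
pooling samples: merged time fractions are averages of per-trial fractions
(a trial without the posture contributes 0), so they need not sum to 100%.
For the per-posture mean score, a trial without the posture has no
per-trial mean at all — and 0 would be a wrong neutral element (AWBA's
floor is 2) — so the mean is taken over the trials where the posture
occurs. This mean-of-means choice mirrors how multi-subject summaries are
conventionally presented for this kind of report.

## The synthetic world

`generate_trial()` renders a script of (posture, duration) segments as
template mean angles + 0.5 s linear transitions + i.i.d. Gaussian jitter
(sd 3°, a realistic wearable-capture wobble) + a 25°/1 Hz knee sinusoid for
carrying (gait). Template angles are package constants chosen to land in
specific scoring bands so expected scores are analytically known — e.g.
stooping's 95° back flexion sits in the top LUBA band (score 12) — they are
*not* measurements. Transition samples take the incoming segment's label.

`bricklaying_script(variant)` emulates a ~120 s construction circuit: 20 s
of carrying, then four cycles of lifting/lowering (5 s), the bricklaying
posture (15 s), and standing recovery (5 s). With the stooping variant the
back flexion/extension wear crosses 0.7 before trial end; the kneeling
variant alternates wear and recovery without saturating. These durations
were fixed from the task phenomenology (carrying until ~20 s, repeated
brick-laying bouts) before any test was run, and are not tuned.

What a green synthetic test establishes: the pipeline's arithmetic,
invariants, and qualitative dynamics. What it does not: classifier accuracy
on real data, the realism of template angles, or any subject-level number
from real recordings (those depend on the original dataset and trained
model and are not reproducible at desk scale).

## Numerical and degenerate-input choices

- Angles validated finite and |angle| ≤ 360°; a missing required motion
  column is a schema error naming the column, never silently neutral.
- Time stamps must be uniform to 1e-6 s at the declared rate; when absent
  they are reconstructed 0-based.
- Empty series: scoring yields empty frames; threshold statistics on an
  empty trajectory are an error (undefined, not zero).
- CSV dialect: comma-separated, UTF-8, mandatory header, columns
  `<joint>_<motion>`; degrees everywhere, no radians in any interface.
- CLI exit codes: 0 success, 2 configuration/validation, 3 I/O.

## Known limitations

- No force/load modelling: the wear index sees posture only, not external
  load, so two workers holding different weights in the same posture wear
  identically.
- The 0.7 threshold and the 240 s calibration come from static, low-force
  assumptions; both are configurable but their field validity is open.
- AWBA on dynamic tasks oscillates with gait; interpret carrying segments
  accordingly.
- Arm selection ("worst") for AULA and the arm tie-break for LUBA are
  package choices where the source methods are silent; flagged for
  calibration if reference outputs ever become available.
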