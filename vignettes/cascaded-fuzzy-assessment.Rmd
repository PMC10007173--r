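---
title: "Cascaded fuzzy assessment of laparoscopic hand movements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascaded fuzzy assessment of laparoscopic hand movements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lapskill)
```

## The assessment problem

During box-trainer exercises such as peg transfer, a trainee's instrument
handling is traditionally graded by a supervising surgeon watching the
scene. `lapskill` automates one specific, well-defined slice of that
judgement: *where the instrument tips are in the 3D workspace*. Two
synchronized cameras watch the trainer — one from above, one from the
front — and an object detector (outside this package's scope) reports a
bounding box per grasper per frame. From those boxes the package measures,
per hand:

* **Dis** — the distance (cm) of the grasper centroid from the centre of
  the *field of interest*, the central board region the hands should work
  over, seen by the top camera;
* **h** — the grasper centroid's height coordinate (cm) in the front
  view. Image coordinates originate at the frame's top-left corner, so
  *smaller h means physically higher*.

There is no exact mathematical model of "good hand position"; the
reference standard is an expert's judgement over vague categories
("too far", "lifted too high"). That is the textbook setting for Mamdani
fuzzy inference: expert knowledge enters as a small rule table over
linguistic labels, and the machinery turns continuous measurements into a
graded score.

## The two-level cascade

Each hand is scored by an identical two-input, one-output Mamdani system
(the task geometry is symmetric, so one rule table serves both hands):

* `distance` over [0, 23] cm with labels **Close / Middle / Far**;
* `height` over [0, 22.5] cm with labels **High / Field / Down**
  (top-to-bottom in the front frame);
* output `hand_score` over [0, 100] % with letter labels **E … A**.

The first-level rule table (rows: height region; columns: distance):

| | Close | Middle | Far |
|---|---|---|---|
| **High** | B | E | E |
| **Field** | A | B | C |
| **Down** | B | B | D |

Working at field height near the centre is ideal (A); lifting the
instrument high while away from the centre is the worst pattern (E),
because a raised, distant instrument is both invisible to the front
camera and out of the working field.

The two crisp scores (SRHPA for the right hand, SLHPA for the left) are
then *refuzzified* — read back onto a coarser three-label variable
{**Bad, Good, Excellent**} — and a second-level system combines them into
the final performance assessment (FPA), again on [0, 100] % with letters
A–E (rows: right hand; columns: left hand):

| | Excellent | Good | Bad |
|---|---|---|---|
| **Excellent** | A | B | C |
| **Good** | B | C | E |
| **Bad** | C | D | D |

This table is encoded exactly as published. Note it is *asymmetric* in
the hands: Good × Bad → E but Bad × Good → D. Whether that asymmetry is
deliberate (for instance, dominant-hand weighting) is not stated in the
source material; `fuzzy$symmetrize_level2 = TRUE` in the configuration
resolves each asymmetric pair to the less severe grade, which also makes
the rule grid monotone (see *Limitations*).

Inference uses the classical Mamdani operator pair — `min` for rule
conjunction, `max` for aggregation per consequent label — with singleton
fuzzification of the crisp inputs.

## Membership functions and their defaults

The source figures show the qualitative shape of the membership functions
but not their breakpoints, so every breakpoint is a configuration value
(`default_config()`; no constants are hidden in code). The shipped
defaults are:

* **Inputs**: three triangular labels per variable with 50% overlap
  spanning the universe; the edge labels are shouldered (a degenerate
  triangle side), so the variable is *complete* — every point of the
  universe carries positive membership and the full rule base always
  fires once inputs are clamped to the universe.
* **Score outputs**: five evenly spaced triangles with peaks at
  10/30/50/70/90 % (E through A).
* **Refuzzified variable**: Bad = trapezoid (0, 0, 10, 50),
  Good = triangle (10, 50, 90), Excellent = trapezoid (50, 90, 100, 100).
  The prototypes align with the E, C and A output peaks, so a first-level
  score at a letter prototype refuzzifies to a *pure* second-level label:
  an all-A pair of hands yields FPA = 90% = A exactly, and the cascade's
  composition behaves like the rule tables read end-to-end. A naive
  0/50/100 placement would break that correspondence (an A-grade 90%
  would fuzzify as only 0.8 Excellent).

Calibration defaults assume 1280 × 720 px frames imaging a
40 × 22.5 cm scene (16:9 preserved, 32 px/cm on both axes), with the
field-of-interest centre at the top-frame centre. The pixel→cm map is a
plain per-axis scale; anisotropic pixels are supported by applying the
scale per axis. True camera calibration (intrinsics, distortion, stereo)
is deliberately out of scope — the measurement model is the same
per-axis division used by the original system.

## Defuzzification

Two methods are implemented, selectable per configuration:

* `center_of_average` (default): the activation-weighted mean of the
  activated labels' prototype abscissae — the discrete weighted-sum
  centroid. With the default MFs this maps a single fully fired rule to
  its consequent peak exactly, which is what makes the rule-table
  prototype tests exact.
* `center_of_gravity`: each consequent MF is clipped at its activation,
  the clipped sets are max-aggregated, and the crisp output is the area
  centroid of the resulting piecewise-linear region. The integration is
  *analytic*: the universe is subdivided at every clipped-polyline vertex
  and every pairwise segment intersection, and x·mu(x) and mu(x) are
  integrated in closed form per linear piece. Tests compare it against an
  independent discrete fine-grid centroid (2 × 10⁵ points); agreement is
  at the 10⁻⁹ relative level, comfortably within the 10⁻⁶ tolerance the
  tests assert.

Letter grades are read back from crisp scores as the label of maximal
membership, with ties broken toward the *worse* grade — a conservative
choice: at an exact crossover the trainee gets the lower letter.

## Missing detections

A detector can miss a hand in either view; the semantics differ:

* **Missing from the front view** (top view present): the instrument has
  been lifted toward the top camera and left the front camera's frustum —
  the characteristic cue is a sudden enlargement of the top-view box.
  The hand's height is therefore set to the **High prototype** (the
  minimal assumption consistent with that geometry), which at Middle or
  Far distance drives the score to E.
* **Missing from the top view**: there is no comparable geometric
  inference, so the last known distance is held for up to
  `fusion$hold_window_frames` frames (default 15, i.e. 0.5 s at 30 FPS);
  beyond the window the hand — and with it the frame's FPA — is
  flagged-skipped and counted in the session summary.

## Stream pairing and hand assignment

The two cameras are treated as independent, time-ordered streams that
must be merged deterministically. Frames are paired by *timestamp*
(robust to index drift between unsynchronized encoders): a greedy
nearest-neighbour sweep within `fusion$pairing_tolerance_s` (default
20 ms ≈ half a frame at 30 FPS), each record used at most once; unmatched
frames are counted, not assessed. Detections below `fusion$min_score`
(default 0.5) are dropped; labelled right/left graspers are taken by
highest score per class, unlabelled ones fall back to x-ordering
(rightmost centroid = right hand). `run_session()` is a pure function of
(streams, configuration) and processes frames one at a time, so memory
stays bounded regardless of session length.

## The synthetic generator

No video data ships with the package; `simulate_session()` generates
detection streams directly. Each hand follows a discrete mean-reverting
(Ornstein–Uhlenbeck) walk around its profile's mean position and height —
the simplest process with a tunable dwell near the field centre —
interrupted by a two-state semi-Markov excursion switch: from calm, an
excursion starts with per-frame probability *p*, lasts a geometric dwell
with mean *m* (stationary excursion occupancy *m*/(*m* + 1/*p*), which
the tests verify), and drives the hand toward a Far (board-edge) or High
(lifted) target. True positions are projected through the calibration to
both cameras and emitted as bounding boxes with centroid jitter,
Beta-distributed confidence scores, false negatives, and — whenever the
true height is in the High band — front-view occlusion with the profile's
probability. Box size grows as the instrument nears the top camera,
mirroring the enlargement cue. A ground-truth sidecar (true Dis/h,
occlusion flags) accompanies every simulation so occlusion semantics can
be tested frame-exactly.

The shipped profiles encode the study conditions: the **expert** works at
the field centre (stationary spread ≈ 1 cm, excursion *p* = 0.005,
*m* = 10), the **novice** sits ~6 cm off-centre with larger jitter and
frequent long excursions (*p* = 0.05, *m* = 20, 5% false negatives), the
**intermediate** between. These are one-time choices of what realistic
skill levels look like on a 40-cm board, not tuning knobs.

What the generator does *not* emulate: photorealistic appearance,
detector-specific error structure (correlated misses, label swaps,
box-aspect pathologies), pegs/objects and transfer events, or camera
desynchronization beyond timestamp jitter. Passing tests therefore
demonstrate the *measurement-and-inference* chain, not detector
robustness on real video.

## Problem sizes and numerical choices

The test suite and the acceptance script use: 27 rule-table prototype
checks; 100 random systems for the defuzzification oracle; 1000 random
input pairs for left/right symmetry; 1000 sampled distances for
monotonicity; 600-frame sessions for occlusion semantics; and 20 seed
pairs × 600 frames for expert/novice separation. Sessions of 600 frames
(20 s at 30 FPS) are long enough for excursion statistics to stabilize
while keeping a full run in tens of seconds.

Other numeric choices: out-of-universe inputs are clamped to the universe
bounds (keeps the complete rule base firing; a distance can exceed the
nominal universe in the frame corners); centroids are continuous (no
pixel rounding); bounding boxes are serialized at fixed precision so
streams round-trip byte-identically; all generator randomness flows from
a single integer seed.

## Limitations

* **The published second-level table is not monotone.** Good × Bad → E
  grades *below* Bad × Bad → D, so improving the right hand from the E
  prototype to the D prototype while the left stays at E lowers the FPA
  from 30% to 20%. This is a faithful rendering of the published rules; a
  regression test documents the dip, and `symmetrize_level2` removes it.
* **Mamdani centre-of-average is only approximately monotone between
  prototypes** even for a monotone rule grid: improving one hand can
  raise a mid-grade rule's firing strength (via `min` with the other
  hand's Bad degree) and dilute the average. With the symmetrized table
  the tests bound these dips below two percentage points along the
  score manifold; at the label prototypes monotonicity is exact.
* The refuzzification step quantizes the first-level score to three
  labels, so the FPA is insensitive to within-label differences between
  hands.
* Scores follow hand *position* only — no completion time, economy of
  motion, collision or grasp events. That is the intended scope: the
  supervisor grades workspace discipline, not task success.
* The detector itself (accuracy, latency, label quality) is outside the
  package; `min_score` filtering and the missing-detection policies are
  the only defences against its errors.
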