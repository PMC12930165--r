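---
title: "Counting nest-box entries and exits by crossing parity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting nest-box entries and exits by crossing parity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestcount)
```

## The counting problem

A top-view camera looks down at a bumblebee nest-box entrance in a
greenhouse. A detector + tracker turns the footage into per-frame bounding
boxes with track IDs. The quantity of interest is colony traffic: how many
bees entered the nest box, how many exited, and when. The difficulty is that
bees do not fly straight: they hover at the entrance, dip towards it and
veer off, emerge briefly and go back down, or fly across the camera's field
of view without interacting with the nest at all. Any region-based counter
that reacts to single boundary events over-counts badly on such traffic.

`nestcount` post-processes the tracks with a virtual-tripwire scheme: a
rectangular *virtual frame* is placed over the entrance, each track's
bounding-box centre is classified inside/outside frame by frame, and the
sequence of inside/outside transitions (*crossings*) per track is reduced to
nest events by a parity rule.

## Model and assumptions

**State, crossings.** The bee's position is its bounding-box centre — the
standard tripwire convention, robust to box-size jitter; the box edges are
not used. Membership in the rectangle is half-open,
$x_\min \le x < x_\max$, $y_\min \le y < y_\max$, so a point exactly on the
shared boundary of "inside" and "outside" belongs to exactly one of them. A
crossing is recorded whenever the state differs between two consecutive
detections of one track, stamped with the later detection's frame (the first
frame at which the new state is observed). No interpolation is attempted
across detection gaps: however many frames the detector skipped, one state
comparison is made, so at most one crossing is recorded per gap. The
alternative — intersecting the inter-detection segment with the boundary —
differs only when one inter-frame step jumps clear across the 150-px-deep
rectangle, which at 240 fps would require implausible speed.

**Episodes.** Crossings of one track are grouped into *episodes*: a new
episode starts at every crossing separated from its predecessor by at least
the gap threshold $\tau$ (in frames). Within an episode all gaps are
$< \tau$. Because crossings are state transitions, directions alternate
within a track, and the state before any crossing is determined by the
track's initial state and the number of preceding crossings.

**Parity rule.** An episode with an odd number of crossings left the bee on
the opposite side of the boundary from where it started: if it went
outside → inside it *entered* the nest (the track ends at the entrance and
the bee descends out of view); inside → outside is an *exit*. An even count
means a turn-back (out–in–out) or a poke-out (in–out–in): no nest event.
For odd counts the start and end states necessarily differ, so the direction
rule is total and unambiguous; the event is stamped with the episode's last
crossing frame, the moment the outcome became decided.

The decision to evaluate parity per *episode* rather than per whole track is
the package's reading of the time-threshold idea, and it is the reading that
produces the documented error structure: shrinking $\tau$ fragments genuine
even-parity turn-backs into odd pieces (false positives rise), while growing
$\tau$ merges genuinely separate visits that share a track ID — the tracker's
ID-merge failure — into even groups (false negatives rise). The threshold
sweep in the acceptance tests reproduces exactly this trade-off.

**Baseline.** The naive counter emits one event per crossing (inward →
entry, outward → exit), with no threshold and no parity. It can never miss a
detected crossing, so whenever every true event produces at least one
crossing its recall is 100% by construction; its precision is whatever the
traffic's turn-back fraction leaves it.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| frame rectangle | 495 × 150 centred | px | matches the camera geometry the package models; configurable per rig |
| image size | 640 × 480 | px | ditto |
| `fps` | 240 | frames/s | fast enough that a bee moves a few px per frame |
| gap threshold $\tau$ | 1.0 s (240 frames) | s | separates hesitation at the entrance (sub-second) from distinct visits; below ~0.25 s turn-backs fragment, above ~2 s merged IDs dominate the error budget |
| matching tolerance | 240 frames | frames | same time scale as $\tau$; a predicted event within 1 s of a true one is the same physical event |

## What the simulator emulates — and what it does not

The generator ([sim_config()], [generate_dataset()]) renders piecewise-linear
waypoint paths at one position per frame, with per-track log-normal speed
(median 3 px/frame, clipped below at 1.5 px/frame so that a pass-over
transits the 150-px-deep rectangle well inside one second), Gaussian centre
jitter (default sd 1 px), optional per-detection dropout, and a nominal
20 × 20 px box with ±10% size jitter (box size is irrelevant to centre-based
counting). Six trajectory topologies cover the behaviours seen at a nest
entrance: direct entry (`A`), dip-and-turn-back (`B`), direct exit (`C`),
poke-out-and-return (`D`), pass-over, and a multi-transition hesitant entry
(`multi_turn`). Turn-back dwells are uniform on 12–96 frames (0.05–0.4 s) —
brief hesitation — with an optional long-dwell mixture on 288–480 frames
(1.2–2 s) to exercise the threshold's false-positive mode. Tracker failures
are applied per track: an ID *switch* splits a trajectory at a uniform
interior detection and relabels the second half; an ID *merge* stitches two
bees onto one ID separated by a 60–180-frame gap (below the default
threshold, the false-negative mode). Ground truth is stamped from the clean
path geometry before noise is applied: the truth is a property of the bee,
not of the detector.

Default pattern weights (A .3, B .2, C .3, D .1, pass-over .1) down-weight
straight passes, reflecting that straight flight is rare at a nest entrance;
they are a modelling choice, not a calibrated fit to any colony.

The simulator does **not** emulate: multi-bee occlusion and detection
swaps between simultaneously visible bees, curved or ballistic flight
kinematics, lighting- or motion-blur-dependent detection confidence, or
diurnal activity structure. Passing tests therefore demonstrate that the
algorithm is correct *given* tracks whose failure modes are ID switches,
ID merges, jitter and dropout — not that any particular detector achieves
such tracks on real footage.

## Numerical and degenerate-input choices

- Half-open membership and the centre convention make the crossing count a
  pure function of a binary state sequence; all geometry reduces to that.
- Fractional pixel coordinates are allowed throughout (the default centred
  rectangle has half-pixel x-edges).
- A single-detection track, or one that never changes state, yields no
  crossings, no episodes, no events, and no candidate unit — it never
  interacted with the frame.
- An empty tracks file is an empty dataset, not an error; an empty event
  collection writes a header-only CSV that round-trips.
- Event matching is greedy in frame order with first-fit tie-breaking.
  Under a single tolerance, with kind and track-lineage compatibility
  partitioning the problem, greedy matching attains the maximum matching
  size; the tests verify this against an exhaustive matcher on small
  instances rather than assuming it.
- Metrics with a zero denominator are `NA` (undefined), never silently 0.
- True negatives need a unit of observation, which event lists alone do not
  define. The package counts one candidate unit per threshold-separated
  episode of every track that touched the frame; a unit with no true and no
  predicted event of its track lineage within its frame span (widened by the
  matching tolerance) is a TN. This gives the parity method genuine
  negatives on turn-back traffic, while the naive counter — which fires on
  every episode it forms — can have none, matching its degenerate
  recall-100/no-negatives profile.
- Track lineage (the pre-switch parent ID) is carried by the simulator and
  used in matching so that predictions made under a switched ID are credited
  against the parent's truth; evaluation stays fair to the corruption.

## Problem sizes

The test suite works at deliberately modest scale: exhaustive oracle checks
over all inside/outside sequences up to length 8, benchmark datasets of
200–1000 tracks (tens of thousands of detections), and 100–1000-case
property loops under fixed seeds. These sizes keep the whole suite
comfortably fast while leaving every code path and failure mode exercised;
nothing in the algorithm scales worse than linearly in detections per track,
so larger videos are a matter of runtime only.

## Known limitations

- Re-identification across ID switches is out of scope: a switch that cuts a
  track exactly at its crossing transition removes the crossing from both
  halves, and no counter downstream of the tracker can recover it. This is
  visible in the simulations as a small recall deficit for *both* methods
  once switches are enabled.
- The virtual frame is a 2-D rectangle; a 3-D (volumetric) counting region
  is not implemented, as a single top-view camera provides no depth.
- Polygonal counting regions and sub-pixel boundary interpolation are not
  implemented.
- The simulator's defaults are plausibility choices, not fits to measured
  flight data; absolute metric values from simulation characterise the
  algorithm under the stated conditions, not any particular greenhouse.
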