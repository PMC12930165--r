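# nestcount

Automated counting of bumblebee (*Bombus*) entries into and exits from a
nest box, from tracked detections in top-view video. Bumblebees are the
workhorse pollinators of greenhouse strawberry production, and the traffic
through the nest-box entrance is the standard proxy for colony foraging
activity — traditionally counted by a person watching the entrance or the
video. `nestcount` is for researchers and growers who already run a detector
+ tracker (e.g. YOLO with ID tracking) on entrance footage and need the last
step: turning per-frame bounding boxes into reliable entry/exit counts.

## The method

A rectangular **virtual frame** is placed over the entrance in image
coordinates (default: 495 × 150 px centred in a 640 × 480 image at 240 fps).
Each track's bounding-box centre is tested against the rectangle; a change of
inside/outside state between consecutive detections is a **crossing**, inward
or outward.

The naive counter treats every crossing as a nest event. But bees rarely fly
straight: they dip into the frame and turn back, poke out and return, or pass
over the frame entirely, so the naive count is dominated by false positives.

The parity algorithm fixes this. Crossings of one track ID are grouped into
**episodes**: consecutive crossings less than a gap threshold *τ* apart
(default *τ* = 1 s = 240 frames) belong together. For an episode with *k*
crossings:

- *k* odd → the bee ended on the other side of the boundary: one nest
  **entry** (outside → inside) or **exit** (inside → outside), stamped at the
  last crossing;
- *k* even → a turn-back or poke-out: **no event**.

The threshold trades errors: too small and genuine turn-backs fragment into
odd pieces (false positives); too large and separate visits sharing one track
ID (tracker ID merges) collapse into even groups (false negatives).

Predictions are scored against ground truth by greedy one-to-one matching
(same track lineage, same kind, within a frame tolerance), giving the
confusion counts behind accuracy = (TP+TN)/(TP+FP+FN+TN),
precision = TP/(TP+FP), recall = TP/(TP+FN), F1 = 2TP/(2TP+FP+FN).

## Worked example

Simulate 200 noise-free entrance trajectories (30% direct entries, 20%
dip-and-turn-back, 30% direct exits, 10% poke-out-and-return, 10%
pass-overs), count with both methods, and compare against the simulator's
ground truth:

```r
library(nestcount)
tab <- run_benchmark(sim_config(n_tracks = 200, jitter_sd = 0, seed = 1))
format_metric_table(tab)
```

```
     method accuracy (%) precision (%) recall (%) F1 (%)
1 yolo_only         41.3          41.3      100.0   58.5
2    parity        100.0         100.0      100.0  100.0
```

The naive counter misses nothing (recall 100%: it cannot ignore a crossing)
but more than half of its events are spurious turn-backs and pass-overs. The
parity algorithm recovers the true event list exactly. With tracker failures
switched on (5% ID switches, 5% ID merges, 10% of turn-back dwells longer
than the 1 s threshold) both methods degrade, but the ranking persists:

```r
tab <- run_benchmark(sim_config(n_tracks = 500, id_switch_prob = 0.05,
                                id_merge_prob = 0.05, long_dwell_prob = 0.10,
                                seed = 1))
format_metric_table(tab)
```

```
     method accuracy (%) precision (%) recall (%) F1 (%)
1 yolo_only         41.2          41.3       99.7   58.4
2    parity         89.0          87.4       95.5   91.3
```

## Command line

A thin CLI over the same functions is installed with the package
(`exec/nestcount`):

```sh
nestcount simulate  --config cfg.yaml --out runs/sim --seed 1
nestcount count     --tracks runs/sim/tracks.csv --method parity --out runs/events.csv
nestcount evaluate  --pred runs/events.csv --truth runs/sim/truth_events.csv --out runs/metrics.csv
nestcount benchmark --config cfg.yaml --out runs/bench
```

Tracks are exchanged as MOT-challenge CSV
(`frame,id,bb_left,bb_top,bb_width,bb_height,conf,x,y,z`), events as
`track_id,kind,frame_index,source` CSV, configuration as YAML; every command
writes a JSON manifest sufficient to reproduce the run.

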