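# trailtrack

Tracking and trajectory analysis of ants on foraging trails.

Nocturnal trunk-trail foragers are filmed from above; an object detector
emits per-frame ant positions `(frame, x, y)` with no identities.
`trailtrack` is for behavioural ecologists who need to turn such
detection tables into identified trajectories and colony-level movement
statistics — and for anyone who wants to validate that pipeline without
field video, using the built-in ground-truth simulator.

## What it computes

**Tracking.** Between consecutive frames, detections in frame *K*
("suppliers") are matched to detections in frame *K*+1 ("receivers") by
solving a minimum-cost transportation problem exactly: cost
`‖p_i − p_j‖ / gate + w_app · appdist`, gating at a plausibility radius,
with dummy birth/death nodes charging `birth_death_cost` for every
unmatched detection. Tracklets coast through missed detections on a
constant-velocity prediction (gaps linearly interpolated and flagged),
and short or non-moving tracklets are pruned as false positives. Cue
extraction (implausible speeds, interior track terminations, ambiguous
assignments) ranks frames for a second round of detector labelling.

**Trajectory analysis.** After ruler/frame-rate calibration:
straightness index **ST = d/L** (net displacement over path length),
average speed (cm/s), travel direction relative to the nest, U-turn
splitting at the deepest penetration point, and an exploration index
from a ~1 cm² visiting grid: cells are scored
`s(c) = (V_max − V(c))/(V_max − 1)` by how few other trajectories share
them, `EI` is the sum over a trajectory's cells and `AEI = EI / #cells ∈
[0, 1]` (1 = the trajectory explored cells no other ant used).

**Statistics.** Beta-mixture modelling of ST with BIC selection of the
number of straightness groups (EM, mean/precision parameterization),
random-intercept linear mixed models (via `lme4`) for speed over the
night and AEI vs ST, and 30-minute-interval comparisons with
Tukey-adjusted pairwise contrasts.

**Simulation.** A seeded trail-scene generator (goal-directed correlated
random walk, von Mises heading noise calibrated per straightness group,
Poisson arrivals, U-turns, detector corruption: jitter / misses / false
positives / merges) plus a tracking evaluator reporting error-free
trajectory fraction, ID switches, wrong/no-ant sample rate and recall.

## Worked example

```r
library(trailtrack)

scene <- simulate_scene(sim_params(arrival = "fixed", n_ants = 60,
                                   duration_s = 240, seed = 7))
fs    <- corrupt_detections(scene, noise_params())   # jitter/miss/FP/merge
trajs <- build_trajectories(fs, track_params())
evaluate_tracking(scene, trajs)
#> <tracking_eval> 57 truth ants, 55 recovered trajectories
#>   error-free: 92.7%  ID switches: 5  wrong/no-ant samples: 2.36%  mean recall: 96.4%

cfg   <- scene$config
kept  <- filter_edge_starts(calibrate_trajectories(trajs, cfg), cfg)$kept
parts <- assign_directions(split_uturns_all(kept, cfg), cfg)
vm    <- visiting_map(parts, cfg)
rec   <- summarize_trajectories(parts, cfg, vm)
head(rec[c("ant_id", "ST", "mean_speed_cm_s", "direction", "AEI")], 4)
#>   ant_id    ST mean_speed_cm_s direction   AEI
#> 1      1 0.945            5.35  outbound 0.436
#> 2      2 0.875            6.12   inbound 0.436
#> 3      3 0.874            6.34   inbound 0.256
#> 4      4 0.727            5.55   inbound 0.436
```

53 complete crossings survive the edge filter (55 analysis trajectories
after U-turn splitting), with median ST 0.86, mean speed 5.21 cm/s and
median AEI 0.31 — ants mostly cross straight at ~5 cm/s, and a fraction
wander into cells few nestmates visit. BIC then chooses the number of
straightness groups (at this small n it prefers 2; the
distribution-scale recovery tests live in the acceptance suite):

```r
sel <- select_k_bic(rec$ST, K_max = 5, seed = 1)
sel$K_best
#> [1] 2
```

The whole chain — including the mixture and mixed-model stages and a
reproducibility manifest — is also available as one call /
one command:

```r
run_pipeline("detections.csv", "config.json", "out/", view = c(600, 160))
```

```sh
Rscript inst/cli/trailtrack.R pipeline --detections d.csv --config c.json \
    --out out/ --view-w 600 --view-h 160 --seed 7
```

`config.json` needs `cm_per_px` (from the in-video ruler) and accepts
`fps`, `start_clock`, `nest_side`, `trail_axis`, `edge_margin_frac`,
`cell_size_cm`.

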