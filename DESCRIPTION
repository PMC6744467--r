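Package: trailtrack
Title: Assignment-Based Tracking and Trajectory Analysis of Ants on Foraging Trails
Version: 0.1.0
Authors@R:
    person("trailtrack", "developers", email = "trailtrack@example.org",
           role = c("aut", "cre"))
Description: Links per-frame ant detections into trajectories by solving a
    minimum-cost transportation (assignment) problem between consecutive video
    frames, with gap bridging, false-positive pruning and hard-frame cue
    extraction for active-learning style detector retraining. Calibrates
    trajectories into physical units, computes movement metrics (straightness
    index, speed, direction, U-turn splitting), trail-occupancy visiting maps
    and per-trajectory exploration indices, and runs the downstream statistics:
    beta-mixture straightness grouping with BIC model selection, linear
    mixed-effects models, and 30-minute-interval comparisons with Tukey
    adjusted contrasts. Includes a seeded synthetic trail-scene simulator with
    ground truth for end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    lme4,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
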