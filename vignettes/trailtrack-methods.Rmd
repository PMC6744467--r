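---
title: "Methods: assignment-based ant tracking and trajectory analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assignment-based ant tracking and trajectory analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trailtrack)
```

## The problem

Nocturnal trunk-trail ants (e.g. *Camponotus* carpenter ants) are filmed
from above as they cross a ~15 cm stretch of trail. An object detector
emits per-frame positions of every ant in view but no identities.
`trailtrack` turns those anonymous detections into identified
trajectories and then into the behavioural quantities that matter for
trail ecology: how straight each crossing is, how fast, in which
direction relative to the nest, and how much of the trail surface each
ant explores relative to its nestmates.

## Frame-to-frame linking as a transportation problem

Between consecutive frames $K$ and $K+1$, every detection in frame $K$
is a *supplier* and every detection in frame $K+1$ a *receiver*. The
dissimilarity of a supplier–receiver pair is

$$c_{ij} = \frac{\lVert p_i - p_j \rVert}{g} + w_a \cdot d_a(i, j),$$

where $g$ is the gating radius (`gate_px`, default 30 px: pairs farther
apart are infeasible), and $d_a$ is the Euclidean distance between
appearance vectors after scaling each dimension by its observed range
(so $d_a \in [0,1]$; the term vanishes when the detector provides no
appearance features). Normalizing the spatial term by $g$ makes the
birth/death penalty scale-free: leaving any detection unmatched costs
`birth_death_cost` (default 1.5), so any within-gate spatial match is
cheaper than a death plus a birth.

The optimal one-to-one partial matching is found exactly: dummy
birth/death nodes make the rectangular problem a square linear
assignment problem, solved with an $O(n^3)$ shortest-augmenting-path
(Jonker–Volgenant style) routine written for this package and verified,
in the test suite, against exhaustive enumeration of all partial
matchings on hundreds of random instances. We deliberately did not
collapse this onto an external solver: the per-pair formulation *is* the
method, and the in-package solver keeps the dual route (solver vs
brute-force oracle) meaningful.

Sequential frame pairs, not a global network flow, are used — the method
is explicitly frame-pair sequential, with temporal robustness coming
from the tracklet layer:

* **miss recovery** — a tracklet that finds no match coasts at a
  constant-velocity predicted head position for up to `max_gap_frames`
  (default 5) frames; when it re-matches, the gap is filled by linear
  interpolation and flagged. The velocity estimate is exponentially
  smoothed (weight 0.3) because raw one-frame differences are dominated
  by localization jitter, and coasting on a jittery velocity is the main
  cause of identity swaps at close interactions.
* **false-positive pruning** — closed tracklets spanning fewer than
  `min_track_frames` frames (default 13 ≈ 0.5 s at 25 fps) or moving
  less than `min_track_disp_px` (default 10 px) net are discarded. This
  implements a strong preference for discarding false detections using
  temporal information rather than detection-confidence thresholds: a
  stationary leaf fleck can be detected for minutes and still be
  removed, while a genuine ant always traverses.

### Error cues and hard-frame selection

Three cues mark frames worth human labelling in a second detector
training round: per-frame steps above the 99.5th percentile of all
steps (speeds at which ants do not walk, so the assignment likely
bridged a detector error); trajectories starting or ending in the view
interior (more than `edge_margin_frac` from every boundary); and
assignment matches whose *margin* — the total-cost increase if that
match were forbidden — falls below 0.05 while another detection lies
within the gate of the same receiver. The percentile and the margin
threshold are package choices; the source method names the cues but
gives no numbers. `select_training_frames()` implements both the
round-one uniform sample and the round-two cue-ranked selection; the
detector itself is out of scope.

## Trajectory filters

Analysis uses only *complete* crossings: trajectories whose first and
last samples lie within `edge_margin_frac` (default 5%) of a trail-axis
boundary. The margin operationalizes "beginning in the middle of the
view", for which no number is stated in the source; 5% of a 15 cm view
is 7.5 mm, roughly one ant length. Completeness is required at both
ends — "made it from one end to the other completely in view" is read
as constraining both the start and the end.

U-turns (complete trajectories entering and exiting at the same end)
are split at the sample of farthest penetration — the global extremum
of the trail-axis coordinate — with the split sample shared by both
parts. For multi-reversal paths the global extremum is the single
defensible "point the trajectory turned"; splitting at every local
reversal would fragment jittery paths. Each part is analysed
individually, with its direction taken from the sign of its net
trail-axis displacement (the part's exit is the turn point, not a view
boundary).

## Metrics

With the ruler calibration (`cm_per_px`) and frame rate applied,
each trajectory yields

* $L$ — path length (sum of consecutive-sample distances, cm), and $d$
  — net displacement (cm);
* straightness $ST = d/L \in [0,1]$ (1 = straight crossing, 0 = returns
  to start); stationary trajectories ($L=0$) are excluded with a logged
  reason;
* average speed $= L / \Delta t$ (cm/s);
* direction (inbound/outbound) from the exit boundary vs the configured
  nest side.

### Visiting map and exploration index

The view is divided into half-open square cells of `cell_size_cm`
(default 1 cm, matching the ~1 cm² grid of the original heatmaps). Every
segment is rasterized with an Amanatides–Woo grid traversal, so a fast
ant skips no cells and the cell path is always edge-connected. Two
counting modes exist: `entries` counts every walk-in event (re-entries
included — the heatmap semantics), `trajectories` counts distinct
trajectories per cell (the exploration semantics).

The per-cell exploration score is

$$s(c) = \begin{cases} \dfrac{V_{\max} - V(c)}{V_{\max} - 1} & V_{\max} > 1 \\ 1 & V_{\max} \le 1 \end{cases}$$

where $V(c)$ is the trajectories-mode count and $V_{\max}$ its maximum
over visited cells. $EI = \sum_c s(c)$ over the distinct cells the
trajectory traverses, and $AEI = EI / \#\text{cells}$. **This formula is
a reimplementation decision**: the original exploration index is defined
in a supplement that is not part of the sources for this package. The
form above satisfies every stated property — low when the trajectory
crosses heavily shared cells, $AEI \in [0, 1]$, 1 for a sole explorer, 0
on maximally shared cells — and dividing by the *cell count* (rather
than metric length) is what bounds AEI in $[0,1]$ exactly. The focal
trajectory is included in its own map, so $V(c) \ge 1$ on its cells.
Maps are computed per video; exploration is always relative to the
traffic in the same recording.

## Statistics

**Straightness groups.** ST values (clamped to $[10^{-4},
1-10^{-4}]$, since 2-sample trajectories reach exactly 1) are modelled
as a $K$-component beta mixture in the mean/precision parameterization
($\alpha_k = \mu_k\phi_k$, $\beta_k = (1-\mu_k)\phi_k$), fitted by EM.
The M-step maximizes the weighted beta log-likelihood through its three
sufficient statistics, starting each component at its current
parameters, so the observed log-likelihood is monotone (generalized
EM; the suite asserts this). Ten seeded restarts (quantile-partition
initialization first, random partitions after) guard against local
optima; convergence is an absolute log-likelihood improvement below
$10^{-8}$ or 500 iterations. $K$ is chosen by BIC
($-2\log L + (3K-1)\log n$) over $K = 1..6$. Component dispersions are
not reported in the source, which gives only weights and means; the
simulation defaults $\phi = (600, 600, 200, 30)$ were chosen once so
that the four groups overlap into the smooth negatively-skewed shape
seen in the published histogram, and recovery tests treat them as the
ground truth of the *simulated* world, not as published values.

**Mixed models.** `fit_lmm()` wraps `lme4::lmer` with random
intercepts (REML). p-values use the normal approximation to the Wald
t — the Satterthwaite machinery of `lmerTest` is not available in the
dependency set, and at thousands of trajectories the difference is
immaterial. The speed model uses a continuous time covariate scaled to
the night span (19:30–00:00), so its slope reads directly as "cm/s per
night". `interval_comparison()` bins trajectories into clock-aligned
30-minute intervals, fits the interval factor as cell means with colony
and date intercepts, and adjusts all pairwise contrasts with the
studentized range (`ptukey`), the classical Tukey method; intervals
with fewer than two observations are dropped with a warning. AEI is
modelled untransformed.

## The simulator: what it emulates and what it does not

`simulate_scene()` states the world the tests run in: a 15 × 4 cm view
at 40 px/cm and 25 fps; Poisson (or fixed/spaced) arrivals at either
end; per-ant speeds from a truncated normal (mean 5.15, sd 1.63,
floor 0.5 cm/s); straightness groups drawn with weights
37.0/26.2/30.0/6.8%; goal-directed correlated random walk with
von Mises heading noise; U-turns by goal reversal at a uniform 25–75%
depth (probability 0.05 by default); lateral reflection at the trail
edges. Arrival rate 0.25 ants/s and the 4 cm width are package choices
of a realistically busy mid-night trail.

The heading-noise concentration per group inverts
$A_1(\kappa) = I_1(\kappa)/I_0(\kappa)$ at the group's target ST: for
i.i.d. von Mises deviations around the goal direction the expected
straightness of a long path is $\approx E[\cos\varepsilon] =
A_1(\kappa)$, so this closed form *is* the noise→ST calibration (edge
reflections and goal reversal push realized ST slightly below target
for the curviest group; the suite checks centring within a tolerance,
and monotonicity of ST in $\kappa$). Detection corruption adds Gaussian
jitter, Bernoulli misses, Poisson false positives, and midpoint merging
of close pairs — the failure modes of a real detector — with mild
defaults because the emulated detector is a good one.

A green tracking test on this world establishes that the linking logic
is correct under known, independently seeded corruption. It does not
establish field accuracy: real videos add appearance changes,
illumination drift, occlusion by debris and congested multi-ant knots
that the simulator does not model. The published field accuracy
(tracking 81.39% error-free on real video) is therefore *not* a target
of any test here; the package's regression guard (≥ 90% error-free on a
200-ant corrupted synthetic scene) is a property of the stated
synthetic world.

## Numerical choices and degenerate inputs

* Assignment infeasibility uses a large finite cost ($10^8$), keeping
  the solver's dual updates finite; the birth/death route (cost 3 for a
  pair) always undercuts it, and the implementation asserts no
  infeasible pair is ever matched.
* Cells are half-open, so a boundary point belongs to exactly one cell;
  points on the far view edge are clamped into the last cell. Exact
  corner crossings in the grid traversal step in x first
  (deterministic tie-break).
* Beta-mixture restarts that collapse a component (weight $< 10^{-6}$)
  or produce a non-finite log-likelihood are discarded; an error is
  raised only if every restart degenerates.
* `split_uturns()` returns trajectories with fewer than 3 samples, or
  with the extremum at an endpoint, unchanged.
* The clock is carried as unwrapped seconds since the start-day
  midnight (23:59 → 24:30 stays monotone across midnight) and is only
  wrapped for display.

## Known limitations

* The exploration-index formula and its normalization are
  reimplementation decisions (above); absolute AEI values are
  comparable within this package only.
* The appearance term accepts any fixed-length feature vector but the
  original appearance features are unspecified; with no features the
  cost is purely spatial.
* One global transportation over all frames (network flow) can beat
  sequential frame pairs in heavy congestion; the sequential design
  follows the source method and keeps cue extraction local.
* `fit_lmm` p-values are Wald-normal; for small designs (tens of
  observations) prefer the reported estimates and standard errors over
  the p-values.
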