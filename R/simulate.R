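# Synthetic trail scenes with ground truth. Ants arrive at either end of a
# ~15 cm trail view, walk a goal-directed correlated random walk whose
# von Mises heading noise is calibrated per straightness group, sometimes
# U-turn, and are observed as noisy detections (jitter, misses, false
# positives, merges of close pairs).

#' Simulation parameters
#'
#' Defaults restate the field conditions of the study system: a ~15 cm
#' stretch of trunk trail viewed from above, 25 fps, per-ant speeds from a
#' truncated normal with mean 5.15 and sd 1.63 cm/s, and four straightness
#' groups with weights 37.0/26.2/30.0/6.8% and mean straightness
#' 0.94/0.88/0.77/0.49.
#'
#' @param trail_length_cm,trail_width_cm view size along/across the trail.
#' @param px_per_cm pixel scale (ruler calibration, inverted).
#' @param fps frames per second.
#' @param duration_s scene duration.
#' @param arrival `"poisson"` (rate `arrival_rate` ants/s), `"fixed"`
#'   (`n_ants` at uniform random times) or `"spaced"` (`n_ants` at regular
#'   spacing, one ant in view at a time for well-separated test scenes).
#' @param arrival_rate Poisson arrival rate (ants/s).
#' @param n_ants ant count for `"fixed"`/`"spaced"` arrivals.
#' @param speed_mean,speed_sd,speed_min truncated-normal speed distribution
#'   (cm/s), truncated below at `speed_min`.
#' @param group_weights straightness-group mixing weights (sum to 1).
#' @param group_st target mean straightness per group; heading-noise
#'   concentration is calibrated so realized ST centres near these.
#' @param uturn_prob probability an ant reverses its goal mid-crossing.
#' @param nest_side `"low"` or `"high"` end of the trail axis.
#' @param start_clock wall-clock time of frame 0.
#' @param seed integer RNG seed.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(trail_length_cm = 15, trail_width_cm = 4,
                       px_per_cm = 40, fps = 25, duration_s = 600,
                       arrival = c("poisson", "fixed", "spaced"),
                       arrival_rate = 0.25, n_ants = NULL,
                       speed_mean = 5.15, speed_sd = 1.63, speed_min = 0.5,
                       group_weights = c(0.370, 0.262, 0.300, 0.068),
                       group_st = c(0.94, 0.88, 0.77, 0.49),
                       uturn_prob = 0.05, nest_side = "low",
                       start_clock = "19:30:00", seed = 1) {
  arrival <- match.arg(arrival)
  stopifnot(trail_length_cm > 0, trail_width_cm > 0, px_per_cm > 0,
            fps > 0, duration_s > 0, arrival_rate > 0, speed_mean > 0,
            speed_sd >= 0, speed_min > 0, uturn_prob >= 0, uturn_prob <= 1,
            length(group_weights) == length(group_st),
            abs(sum(group_weights) - 1) < 1e-8,
            all(group_st > 0), all(group_st <= 1))
  if (arrival != "poisson" && is.null(n_ants))
    stop("n_ants is required for '", arrival, "' arrivals")
  structure(list(trail_length_cm = trail_length_cm,
                 trail_width_cm = trail_width_cm, px_per_cm = px_per_cm,
                 fps = fps, duration_s = duration_s, arrival = arrival,
                 arrival_rate = arrival_rate, n_ants = n_ants,
                 speed_mean = speed_mean, speed_sd = speed_sd,
                 speed_min = speed_min, group_weights = group_weights,
                 group_st = group_st, uturn_prob = uturn_prob,
                 nest_side = nest_side, start_clock = start_clock,
                 seed = seed),
            class = "sim_params")
}

#' Noise parameters for detection corruption
#'
#' Defaults are mild, emulating a detector that tolerates some false
#' positives to keep misses very low.
#'
#' @param jitter_px sd of Gaussian localization noise per coordinate.
#' @param miss_rate probability a detection is dropped.
#' @param fp_rate expected false positives per frame (uniform over view).
#' @param merge_dist_px detection pairs closer than this are merged to
#'   their midpoint (densely clustered ants seen as one instance).
#' @return object of class `noise_params`.
#' @export
noise_params <- function(jitter_px = 1, miss_rate = 0.02, fp_rate = 0.05,
                         merge_dist_px = 6) {
  stopifnot(jitter_px >= 0, miss_rate >= 0, miss_rate <= 1,
            fp_rate >= 0, merge_dist_px >= 0)
  structure(list(jitter_px = jitter_px, miss_rate = miss_rate,
                 fp_rate = fp_rate, merge_dist_px = merge_dist_px),
            class = "noise_params")
}

# von Mises concentration with mean resultant length A1(kappa) = r.
# For i.i.d. heading errors eps around the goal direction, the expected
# straightness of a long path is ~ E[cos eps] = A1(kappa), so this is the
# noise -> ST calibration.
kappa_for_st <- function(st) {
  if (st >= 1 - 1e-9) return(Inf)
  if (st <= 1e-9) return(0)
  a1 <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE)
  stats::uniroot(function(k) a1(k) - st, c(1e-6, 1e4), tol = 1e-10)$root
}

# batch von Mises sampler, mean 0 (Best & Fisher 1979 rejection), vectorized
.rvonmises <- function(n, kappa) {
  if (n == 0) return(numeric(0))
  if (!is.finite(kappa) || kappa > 1e6) return(rep(0, n))
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(n - length(out), 16L)
    m2 <- ceiling(m * 1.5)
    u1 <- runif(m2); u2 <- runif(m2); u3 <- runif(m2)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    out <- c(out, (sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))))
  }
  out[seq_len(n)]
}

.rtruncnorm <- function(n, mean, sd, lower) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n, mean, sd)
    out <- c(out, x[x > lower])
  }
  out[seq_len(n)]
}

# fold a coordinate into [0, w] by reflection
.reflect <- function(y, w) {
  z <- y %% (2 * w)
  ifelse(z > w, 2 * w - z, z)
}

#' Simulate a trail scene with ground truth
#'
#' Ants arrive at a random trail-axis end and walk toward the opposite end
#' as a goal-attracted correlated random walk: each per-frame step has
#' length `speed / fps` and heading equal to the goal direction plus a
#' von Mises deviation whose concentration is set by the ant's straightness
#' group ([kappa_for_st()]). Lateral position reflects off the trail edges.
#' With probability `uturn_prob` an ant reverses its goal at a random depth
#' (25-75% of the trail length), producing a U-turn. The same seed
#' reproduces the scene exactly.
#'
#' @param p a [sim_params()].
#' @return object of class `sim_scene`: `truth` (list of `ant_trajectory`
#'   with group/speed/U-turn metadata), `truth_df` (long table
#'   `ant, frame, x_px, y_px, group, uturn`), `detections` (clean detection
#'   table), `fs_clean` (a [frame_set()]), `config` (a matching
#'   [trail_config()]), `params`.
#' @export
simulate_scene <- function(p = sim_params()) {
  set.seed(p$seed)
  L <- p$trail_length_cm; W <- p$trail_width_cm
  view_px <- c(L, W) * p$px_per_cm
  step_mean <- p$speed_mean / p$fps

  arrivals <- switch(p$arrival,
    poisson = {
      tt <- cumsum(rexp(ceiling(p$arrival_rate * p$duration_s * 3) + 10,
                        p$arrival_rate))
      tt[tt < p$duration_s]
    },
    fixed = sort(runif(p$n_ants, 0, p$duration_s)),
    spaced = seq(0, p$duration_s, length.out = p$n_ants + 1L)[seq_len(p$n_ants)]
  )
  n <- length(arrivals)
  if (n == 0) stop("no ants arrived; increase duration or rate")

  groups <- sample(seq_along(p$group_weights), n, replace = TRUE,
                   prob = p$group_weights)
  kappas <- vapply(p$group_st, kappa_for_st, numeric(1))
  speeds <- .rtruncnorm(n, p$speed_mean, p$speed_sd, p$speed_min)
  enter_low <- runif(n) < 0.5
  uturns <- runif(n) < p$uturn_prob
  lat0 <- runif(n, 0.1 * W, 0.9 * W)

  truth <- vector("list", n)
  det_rows <- vector("list", n)
  for (i in seq_len(n)) {
    v <- speeds[i]; kap <- kappas[groups[i]]
    step <- v / p$fps
    max_steps <- min(20000L, ceiling(20 * L / step))
    eps <- .rvonmises(max_steps, kap)
    dirn <- if (enter_low[i]) 1 else -1
    along0 <- if (enter_low[i]) 0 else L
    d_along <- step * cos(eps)
    d_lat <- step * sin(eps)
    turn_depth <- if (uturns[i]) runif(1, 0.25, 0.75) * L else Inf
    along <- along0 + cumsum(dirn * d_along)
    depth <- dirn * (along - along0)
    ti <- which(depth >= turn_depth)[1]
    if (!is.na(ti) && ti < max_steps) {
      rest <- (ti + 1L):max_steps
      along[rest] <- along[ti] - cumsum(dirn * d_along[rest])
    }
    out_i <- which(along < 0 | along > L)[1]
    n_steps <- if (is.na(out_i)) max_steps else out_i - 1L
    if (n_steps < 1L) next
    keep <- seq_len(n_steps)
    lat <- .reflect(lat0[i] + cumsum(d_lat[keep]), W)
    f0 <- round(arrivals[i] * p$fps)
    frames <- f0 + c(0L, keep)
    x_cm <- c(along0, along[keep]); y_cm <- c(lat0[i], lat)
    # drop samples past the scene end
    inwin <- frames <= ceiling(p$duration_s * p$fps) + 20 * p$fps
    frames <- frames[inwin]; x_cm <- x_cm[inwin]; y_cm <- y_cm[inwin]
    if (length(frames) < 2) next
    x_px <- pmin(pmax(x_cm * p$px_per_cm, 0), view_px[1])
    y_px <- pmin(pmax(y_cm * p$px_per_cm, 0), view_px[2])
    truth[[i]] <- ant_trajectory(
      i, data.frame(frame = frames, x_px = x_px, y_px = y_px,
                    interpolated = FALSE),
      view_px = view_px,
      meta = list(group = groups[i], speed_cm_s = v, uturn = uturns[i],
                  entered_low = enter_low[i]))
    det_rows[[i]] <- data.frame(frame = frames, x_px = x_px, y_px = y_px,
                                ant = i)
  }
  ok <- !vapply(truth, is.null, logical(1))
  truth <- truth[ok]
  # relabel 1..n_kept
  for (j in seq_along(truth)) truth[[j]]$ant_id <- j
  det_rows <- det_rows[ok]
  for (j in seq_along(det_rows)) det_rows[[j]]$ant <- j
  det <- do.call(rbind, det_rows)
  truth_df <- det
  truth_df$group <- rep(groups[ok], vapply(det_rows, nrow, integer(1)))
  truth_df$uturn <- rep(uturns[ok], vapply(det_rows, nrow, integer(1)))
  fs <- frame_set(det[c("frame", "x_px", "y_px")], view_px[1], view_px[2],
                  p$fps)
  cfg <- trail_config(cm_per_px = 1 / p$px_per_cm, fps = p$fps,
                      start_clock = p$start_clock, nest_side = p$nest_side,
                      trail_axis = "x")
  structure(list(truth = truth, truth_df = truth_df,
                 detections = det, fs_clean = fs, config = cfg, params = p),
            class = "sim_scene")
}

#' @export
print.sim_scene <- function(x, ...) {
  cat(sprintf("<sim_scene> %d ants, %d clean detections, seed %d\n",
              length(x$truth), nrow(x$detections), x$params$seed))
  invisible(x)
}

#' Corrupt clean detections into a realistic detector output
#'
#' Applies, in order: Gaussian localization jitter, random misses, uniform
#' false positives (Poisson per frame) and merging of detection pairs
#' closer than `merge_dist_px` into their midpoint (densely clustered ants
#' detected as one instance).
#'
#' @param scene a [simulate_scene()] result.
#' @param noise a [noise_params()].
#' @param seed RNG seed (default: scene seed + 1).
#' @return a [frame_set()] of corrupted detections.
#' @export
corrupt_detections <- function(scene, noise = noise_params(), seed = NULL) {
  if (is.null(seed)) seed <- scene$params$seed + 1L
  set.seed(seed)
  det <- scene$detections[c("frame", "x_px", "y_px")]
  vw <- scene$fs_clean$view_width_px; vh <- scene$fs_clean$view_height_px
  nfr <- max(det$frame) + 1L
  if (noise$jitter_px > 0 && nrow(det)) {
    det$x_px <- pmin(pmax(det$x_px + rnorm(nrow(det), 0, noise$jitter_px), 0), vw)
    det$y_px <- pmin(pmax(det$y_px + rnorm(nrow(det), 0, noise$jitter_px), 0), vh)
  }
  if (noise$miss_rate > 0 && nrow(det))
    det <- det[runif(nrow(det)) >= noise$miss_rate, , drop = FALSE]
  if (noise$fp_rate > 0) {
    nfp <- rpois(nfr, noise$fp_rate)
    tot <- sum(nfp)
    if (tot > 0) {
      fp <- data.frame(frame = rep(seq_len(nfr) - 1L, nfp),
                       x_px = runif(tot, 0, vw), y_px = runif(tot, 0, vh))
      det <- rbind(det, fp)
    }
  }
  if (noise$merge_dist_px > 0 && nrow(det)) {
    det <- det[order(det$frame), , drop = FALSE]
    pieces <- split(det, det$frame)
    pieces <- lapply(names(pieces), function(fch) {
      d <- pieces[[fch]]
      xy <- as.matrix(d[, c("x_px", "y_px")])
      while (nrow(xy) >= 2) {  # greedily merge the closest pair
        dm <- as.matrix(dist(xy))
        diag(dm) <- Inf
        mn <- which(dm == min(dm), arr.ind = TRUE)[1, ]
        if (dm[mn[1], mn[2]] >= noise$merge_dist_px) break
        mid <- colMeans(xy[c(mn[1], mn[2]), , drop = FALSE])
        xy <- rbind(xy[-c(mn[1], mn[2]), , drop = FALSE], mid)
      }
      data.frame(frame = as.integer(fch), x_px = xy[, 1], y_px = xy[, 2])
    })
    det <- do.call(rbind, pieces)
  }
  frame_set(det, vw, vh, scene$params$fps)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
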