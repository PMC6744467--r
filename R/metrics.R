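# Per-trajectory movement metrics: path length, net displacement,
# straightness index ST = d/L, average speed.

#' Path length and net displacement
#'
#' `L` is the sum of Euclidean distances between consecutive samples, `d`
#' the Euclidean distance from the first to the last sample, both in cm.
#'
#' @param t a calibrated `ant_trajectory` with at least 2 samples.
#' @return named numeric `c(L_cm, d_cm)`.
#' @export
path_length_and_displacement <- function(t) {
  s <- t$samples
  if (is.null(s$x_cm)) stop("trajectory is not calibrated")
  if (nrow(s) < 2) stop("need at least 2 samples")
  L <- sum(sqrt(diff(s$x_cm)^2 + diff(s$y_cm)^2))
  d <- sqrt((s$x_cm[nrow(s)] - s$x_cm[1])^2 + (s$y_cm[nrow(s)] - s$y_cm[1])^2)
  c(L_cm = L, d_cm = d)
}

#' Straightness index
#'
#' `ST = d / L`: the ratio of net displacement to total path length. 1 for
#' a perfectly straight monotone path, 0 for a path returning to its start;
#' invariant under rotation, translation and uniform scaling. A stationary
#' trajectory (`L = 0`) has undefined straightness and returns `NA` with a
#' message; callers exclude it.
#'
#' @param t a calibrated `ant_trajectory`.
#' @return ST in \[0, 1\], or `NA` when `L = 0`.
#' @export
straightness <- function(t) {
  ld <- path_length_and_displacement(t)
  if (ld[["L_cm"]] <= 0) {
    message("trajectory ", t$ant_id, " is stationary (L = 0); ST undefined")
    return(NA_real_)
  }
  min(ld[["d_cm"]] / ld[["L_cm"]], 1)
}

#' Average speed
#'
#' Total path length over the time spent in view, in cm/s.
#'
#' @param t a calibrated `ant_trajectory`.
#' @return speed in cm/s.
#' @export
average_speed <- function(t) {
  s <- t$samples
  if (is.null(s$t_s)) stop("trajectory is not calibrated")
  dt <- s$t_s[nrow(s)] - s$t_s[1]
  if (dt <= 0) stop("zero-duration trajectory")
  path_length_and_displacement(t)[["L_cm"]] / dt
}

#' Per-trajectory metric table
#'
#' Computes the full metric record for each trajectory: net displacement,
#' path length, straightness, mean speed, direction, exploration indices
#' (from a trajectories-mode [visiting_map()]), U-turn part, completeness
#' and clock times. Stationary trajectories (undefined ST) are dropped and
#' listed in the `excluded` attribute.
#'
#' @param trajs list of calibrated trajectories.
#' @param cfg a [trail_config()].
#' @param vm optional [visiting_map()] built from `trajs` (trajectories
#'   mode); when `NULL` it is computed here.
#' @return data.frame, one row per trajectory, with attribute `excluded`.
#' @export
summarize_trajectories <- function(trajs, cfg, vm = NULL) {
  if (!length(trajs))
    return(structure(data.frame(
      ant_id = integer(0), d_cm = numeric(0), L_cm = numeric(0),
      ST = numeric(0), mean_speed_cm_s = numeric(0), direction = character(0),
      EI = numeric(0), AEI = numeric(0), uturn_part = character(0),
      complete = logical(0), start_clock = character(0),
      end_clock = character(0), clock_s = numeric(0)),
      excluded = data.frame(ant_id = integer(0), reason = character(0))))
  if (is.null(vm)) vm <- visiting_map(trajs, cfg, mode = "trajectories")
  rows <- list(); excl <- list()
  for (t in trajs) {
    ld <- path_length_and_displacement(t)
    if (ld[["L_cm"]] <= 0) {
      excl[[length(excl) + 1L]] <- data.frame(ant_id = t$ant_id,
                                              reason = "stationary")
      next
    }
    ei <- exploration_index(t, vm)
    s <- t$samples
    rows[[length(rows) + 1L]] <- data.frame(
      ant_id = t$ant_id, d_cm = ld[["d_cm"]], L_cm = ld[["L_cm"]],
      ST = min(ld[["d_cm"]] / ld[["L_cm"]], 1),
      mean_speed_cm_s = average_speed(t), direction = t$direction,
      EI = ei[["EI"]], AEI = ei[["AEI"]], uturn_part = t$uturn_part,
      complete = t$complete,
      start_clock = .s_to_clock(s$clock_s[1]),
      end_clock = .s_to_clock(s$clock_s[nrow(s)]),
      clock_s = s$clock_s[1])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(ant_id = integer(0), reason = character(0))
  out
}
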