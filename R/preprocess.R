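# Calibration into physical units and the trajectory-level filters applied
# before analysis: keep only complete edge-to-edge crossings, split U-turns
# at the turn point, assign travel direction relative to the nest.

# trail-axis pixel coordinate and extent of a trajectory's view
.axis_px <- function(t, cfg) {
  if (cfg$trail_axis == "x") list(coord = t$samples$x_px, extent = t$view_px[1])
  else list(coord = t$samples$y_px, extent = t$view_px[2])
}

#' Calibrate a trajectory into seconds, wall clock and centimetres
#'
#' Adds `t_s = frame / fps`, `clock_s = start_clock + t_s`,
#' `x_cm = x_px * cm_per_px`, `y_cm = y_px * cm_per_px` to every sample.
#'
#' @param t an `ant_trajectory`.
#' @param cfg a [trail_config()].
#' @return the calibrated trajectory.
#' @export
calibrate_trajectory <- function(t, cfg) {
  s <- t$samples
  s$t_s <- s$frame / cfg$fps
  s$clock_s <- cfg$start_clock_s + s$t_s
  s$x_cm <- s$x_px * cfg$cm_per_px
  s$y_cm <- s$y_px * cfg$cm_per_px
  t$samples <- s
  t
}

#' @rdname calibrate_trajectory
#' @param trajs list of trajectories.
#' @export
calibrate_trajectories <- function(trajs, cfg)
  lapply(trajs, calibrate_trajectory, cfg = cfg)

# which boundary ("low"/"high"/NA) a trail-axis coordinate is at
.boundary_of <- function(coord, extent, margin_frac) {
  m <- margin_frac * extent
  if (coord <= m) "low" else if (coord >= extent - m) "high" else NA_character_
}

#' Keep only complete edge-to-edge crossings
#'
#' A trajectory is kept when its first and last samples both lie within
#' `edge_margin_frac` of a trail-axis boundary; trajectories that begin or
#' end in the middle of the view (detector dropouts, partial tracks) are
#' removed. Kept trajectories are flagged `complete`. A U-turn that enters
#' and exits at the same edge is complete.
#'
#' @param trajs list of calibrated `ant_trajectory`.
#' @param cfg a [trail_config()].
#' @return list with `kept`, `removed` (trajectory lists) and `report`
#'   (data.frame `ant_id, reason` with reasons `midview_start`/`midview_end`).
#' @export
filter_edge_starts <- function(trajs, cfg) {
  kept <- list(); removed <- list()
  report <- list()
  for (t in trajs) {
    ax <- .axis_px(t, cfg)
    b0 <- .boundary_of(ax$coord[1], ax$extent, cfg$edge_margin_frac)
    b1 <- .boundary_of(ax$coord[length(ax$coord)], ax$extent,
                       cfg$edge_margin_frac)
    if (is.na(b0)) {
      removed[[length(removed) + 1L]] <- t
      report[[length(report) + 1L]] <- data.frame(ant_id = t$ant_id,
                                                  reason = "midview_start")
    } else if (is.na(b1)) {
      removed[[length(removed) + 1L]] <- t
      report[[length(report) + 1L]] <- data.frame(ant_id = t$ant_id,
                                                  reason = "midview_end")
    } else {
      t$complete <- TRUE
      kept[[length(kept) + 1L]] <- t
    }
  }
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(ant_id = integer(0), reason = character(0))
  list(kept = kept, removed = removed, report = report)
}

#' Split a U-turning trajectory at its turn point
#'
#' A complete trajectory entering and exiting at the same trail-axis
#' boundary is a U-turn; it is split into two parts at the sample of
#' farthest penetration (the global extremum of the trail-axis coordinate),
#' which belongs to both parts. Trajectories crossing end-to-end, or with
#' fewer than 3 samples, are returned unchanged.
#'
#' @param t a calibrated, complete `ant_trajectory`.
#' @param cfg a [trail_config()].
#' @return list of 1 or 2 trajectories; parts carry `uturn_part`
#'   `"first"`/`"second"`.
#' @export
split_uturns <- function(t, cfg) {
  s <- t$samples
  if (nrow(s) < 3) return(list(t))
  ax <- .axis_px(t, cfg)
  b0 <- .boundary_of(ax$coord[1], ax$extent, cfg$edge_margin_frac)
  b1 <- .boundary_of(ax$coord[length(ax$coord)], ax$extent,
                     cfg$edge_margin_frac)
  if (is.na(b0) || is.na(b1) || b0 != b1) return(list(t))
  k <- if (b0 == "low") which.max(ax$coord) else which.min(ax$coord)
  if (k <= 1L || k >= nrow(s)) return(list(t))  # degenerate turn at an end
  t1 <- t; t2 <- t
  t1$samples <- s[seq_len(k), , drop = FALSE]
  t2$samples <- s[k:nrow(s), , drop = FALSE]
  rownames(t1$samples) <- rownames(t2$samples) <- NULL
  t1$uturn_part <- "first"; t2$uturn_part <- "second"
  list(t1, t2)
}

#' @rdname split_uturns
#' @param trajs list of trajectories.
#' @export
split_uturns_all <- function(trajs, cfg)
  do.call(c, lapply(trajs, split_uturns, cfg = cfg))

#' Assign travel direction relative to the nest
#'
#' Direction is read off where the ant exited the view: exiting on the nest
#' side is `inbound`, on the opposite side `outbound`; a trajectory not
#' ending at a boundary is `unknown`. For U-turn parts the exit is the turn
#' point, so the part's direction comes from the sign of its net trail-axis
#' displacement.
#'
#' @param t a calibrated `ant_trajectory`.
#' @param cfg a [trail_config()].
#' @return the trajectory with `direction` set.
#' @export
assign_direction <- function(t, cfg) {
  ax <- .axis_px(t, cfg)
  if (t$uturn_part != "none") {
    net <- ax$coord[length(ax$coord)] - ax$coord[1]
    exit_side <- if (net > 0) "high" else "low"
    t$direction <- if (exit_side == cfg$nest_side) "inbound" else "outbound"
    return(t)
  }
  b1 <- .boundary_of(ax$coord[length(ax$coord)], ax$extent,
                     cfg$edge_margin_frac)
  t$direction <- if (is.na(b1)) "unknown"
  else if (b1 == cfg$nest_side) "inbound" else "outbound"
  t
}

#' @rdname assign_direction
#' @param trajs list of trajectories.
#' @export
assign_directions <- function(trajs, cfg)
  lapply(trajs, assign_direction, cfg = cfg)
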