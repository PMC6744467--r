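# Exponential smoothing weight for the per-tracklet velocity estimate;
# damps localization jitter so coasting predictions stay on course.
.VEL_ALPHA <- 0.3

# Sequential frame-pair tracking: active tracklet heads compete in each
# frame's assignment; misses coast on constant-velocity prediction up to
# max_gap_frames, bridged gaps are filled by linear interpolation, and
# short/low-displacement tracklets are pruned as false positives.

#' Build trajectories from a detection frame set
#'
#' Processes frames in order. At each frame the heads of active tracklets
#' (at their constant-velocity predicted positions) are the suppliers and
#' the frame's detections the receivers of a minimum-cost assignment
#' ([solve_frame_assignment()]). Tracklet velocity is exponentially
#' smoothed (weight 0.3) so localization jitter does not steer the
#' prediction. A tracklet that misses its match survives
#' up to `max_gap_frames` frames before being closed; when it re-matches,
#' the skipped frames are filled by linear interpolation and flagged
#' `interpolated`. Closed tracklets spanning fewer than `min_track_frames`
#' frames or moving less than `min_track_disp_px` net are discarded
#' (false-positive pruning). Survivors get sequential `ant_id`s in order of
#' first appearance.
#'
#' @param fs a [frame_set()].
#' @param p a [track_params()].
#' @return list of `ant_trajectory` in pixel coordinates.
#' @export
build_trajectories <- function(fs, p = track_params()) {
  det <- fs$detections
  if (nrow(det) == 0) return(list())
  app_cols <- fs$app_cols
  app_scale <- if (length(app_cols)) {
    vapply(app_cols, function(cc) diff(range(det[[cc]])), numeric(1))
  } else NULL
  by_frame <- split(seq_len(nrow(det)), det$frame)
  f_min <- min(det$frame); f_max <- max(det$frame)

  active <- list()   # each: fr, x, y, interp (vectors), vx, vy, misses, app row, born
  closed <- list()
  n_created <- 0L

  close_track <- function(tr) closed[[length(closed) + 1L]] <<- tr

  for (f in f_min:f_max) {
    rows <- by_frame[[as.character(f)]]
    dets <- det[rows, , drop = FALSE]
    na <- length(active); nd <- nrow(dets)
    if (na == 0L && nd == 0L) next

    if (na) {
      last_fr <- vapply(active, function(t) t$fr[length(t$fr)], numeric(1))
      heads <- data.frame(
        x_px = vapply(active, function(t)
          t$x[length(t$x)] + t$vx * (f - t$fr[length(t$fr)]), numeric(1)),
        y_px = vapply(active, function(t)
          t$y[length(t$y)] + t$vy * (f - t$fr[length(t$fr)]), numeric(1)))
      if (length(app_cols))
        for (k in seq_along(app_cols))
          heads[[app_cols[k]]] <- vapply(active, function(t) t$app[k], numeric(1))
    } else heads <- data.frame(x_px = numeric(0), y_px = numeric(0))

    res <- solve_frame_assignment(heads, dets, p, app_cols, app_scale)

    matched_tracks <- res$matches$i
    survivors <- list()
    if (nrow(res$matches)) {
      for (r in seq_len(nrow(res$matches))) {
        ti <- res$matches$i[r]; dj <- res$matches$j[r]
        tr <- active[[ti]]
        lf <- tr$fr[length(tr$fr)]
        nx <- dets$x_px[dj]; ny <- dets$y_px[dj]
        gap <- f - lf
        if (gap > 1L) {  # bridge the miss gap by linear interpolation
          gf <- (lf + 1L):(f - 1L)
          w <- (gf - lf) / gap
          tr$fr <- c(tr$fr, gf)
          tr$x <- c(tr$x, tr$x[length(tr$x)] * (1 - w) + nx * w)
          tr$y <- c(tr$y, tr$y[length(tr$y)] * (1 - w) + ny * w)
          tr$interp <- c(tr$interp, rep(TRUE, length(gf)))
        }
        tr$fr <- c(tr$fr, f); tr$x <- c(tr$x, nx); tr$y <- c(tr$y, ny)
        tr$interp <- c(tr$interp, FALSE)
        tr$n_matched <- tr$n_matched + 1L
        nlen <- length(tr$fr)
        prev_real <- max(which(!tr$interp[-nlen]))
        dfr <- tr$fr[nlen] - tr$fr[prev_real]
        vix <- (tr$x[nlen] - tr$x[prev_real]) / dfr
        viy <- (tr$y[nlen] - tr$y[prev_real]) / dfr
        if (tr$n_matched <= 2L) { # first link: no prior velocity to smooth
          tr$vx <- vix; tr$vy <- viy
        } else {                  # EMA-smoothed velocity for stabler coasting
          tr$vx <- (1 - .VEL_ALPHA) * tr$vx + .VEL_ALPHA * vix
          tr$vy <- (1 - .VEL_ALPHA) * tr$vy + .VEL_ALPHA * viy
        }
        tr$misses <- 0L
        if (length(app_cols))
          tr$app <- as.numeric(dets[dj, app_cols])
        survivors[[length(survivors) + 1L]] <- tr
      }
    }
    if (na) {
      for (ti in setdiff(seq_len(na), matched_tracks)) {
        tr <- active[[ti]]
        tr$misses <- tr$misses + 1L
        if (tr$misses > p$max_gap_frames) close_track(tr)
        else survivors[[length(survivors) + 1L]] <- tr
      }
    }
    if (length(res$births)) {
      for (dj in res$births) {
        n_created <- n_created + 1L
        survivors[[length(survivors) + 1L]] <- list(
          fr = f, x = dets$x_px[dj], y = dets$y_px[dj], interp = FALSE,
          vx = 0, vy = 0, misses = 0L, n_matched = 1L,
          app = if (length(app_cols)) as.numeric(dets[dj, app_cols]) else NULL,
          born = n_created)
      }
    }
    active <- survivors
  }
  for (tr in active) close_track(tr)

  # prune false positives: short span or low net displacement
  keep <- Filter(function(tr) {
    span <- tr$fr[length(tr$fr)] - tr$fr[1] + 1L
    disp <- sqrt((tr$x[length(tr$x)] - tr$x[1])^2 +
                 (tr$y[length(tr$y)] - tr$y[1])^2)
    span >= p$min_track_frames && disp >= p$min_track_disp_px &&
      length(tr$fr) >= 2L
  }, closed)
  if (!length(keep)) return(list())
  ord <- order(vapply(keep, function(t) t$fr[1], numeric(1)),
               vapply(keep, function(t) t$born, numeric(1)))
  keep <- keep[ord]
  lapply(seq_along(keep), function(i) {
    tr <- keep[[i]]
    ant_trajectory(i, data.frame(frame = as.integer(tr$fr), x_px = tr$x,
                                 y_px = tr$y, interpolated = tr$interp),
                   view_px = c(fs$view_width_px, fs$view_height_px))
  })
}
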