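# Error cues for hard-frame mining: implausibly fast steps, trajectories
# terminating in the view interior, and ambiguous assignments at close
# interactions. Used to pick frames for a second round of detector
# labelling.

#' Extract tracking-error cues
#'
#' Emits three cue types mirroring the failure modes of detector+tracker
#' pipelines:
#' * `speed`: a per-frame step (px/frame) exceeding the 99.5th percentile
#'   of all observed steps — a fast jump suggested by the assignment often
#'   means a detection error;
#' * `interior_termination`: a trajectory starting or ending farther than
#'   `edge_margin_frac` of the view extent from every view boundary — a
#'   track that dies mid-branch suggests missed detections;
#' * `ambiguity`: an assignment match whose cost margin (increase of the
#'   optimal total if the match were forbidden) is below `margin_thresh`
#'   while another detection lies within the gate of the same receiver —
#'   small dissimilarity changes would flip the solution, the signature of
#'   an imminent ID switch.
#'
#' @param fs the [frame_set()] the trajectories were built from.
#' @param trajs list of `ant_trajectory` from [build_trajectories()].
#' @param cfg a [trail_config()] (edge margin).
#' @param p the [track_params()] used for tracking.
#' @param speed_pctl percentile of step lengths above which a step is a cue.
#' @param margin_thresh ambiguity margin threshold in normalized cost units.
#' @return data.frame `cue_type, frame, x_px, y_px, magnitude`.
#' @export
extract_cues <- function(fs, trajs, cfg, p = track_params(),
                         speed_pctl = 99.5, margin_thresh = 0.05) {
  cues <- list()
  add <- function(type, frame, x, y, mag)
    cues[[length(cues) + 1L]] <<- data.frame(
      cue_type = type, frame = as.integer(frame), x_px = x, y_px = y,
      magnitude = mag)

  ## (i) speed cues
  steps <- lapply(trajs, function(t) {
    s <- t$samples
    if (nrow(s) < 2) return(NULL)
    d <- sqrt(diff(s$x_px)^2 + diff(s$y_px)^2) / diff(s$frame)
    data.frame(frame = s$frame[-1], x_px = s$x_px[-1], y_px = s$y_px[-1],
               step = d)
  })
  steps <- do.call(rbind, steps)
  if (!is.null(steps) && nrow(steps)) {
    thr <- quantile(steps$step, speed_pctl / 100, names = FALSE)
    fast <- steps[steps$step > thr, , drop = FALSE]
    if (nrow(fast))
      add("speed", fast$frame, fast$x_px, fast$y_px, fast$step)
  }

  ## (ii) interior termination cues
  w <- fs$view_width_px; h <- fs$view_height_px
  mx <- cfg$edge_margin_frac * w; my <- cfg$edge_margin_frac * h
  for (t in trajs) {
    s <- t$samples
    for (idx in c(1L, nrow(s))) {
      dx <- min(s$x_px[idx], w - s$x_px[idx])
      dy <- min(s$y_px[idx], h - s$y_px[idx])
      if (dx > mx && dy > my)
        add("interior_termination", s$frame[idx], s$x_px[idx], s$y_px[idx],
            min(dx, dy))
    }
  }

  ## (iii) ambiguity cues: re-solve crowded frame pairs with margins
  det <- fs$detections
  frames <- sort(unique(det$frame))
  app_cols <- fs$app_cols
  app_scale <- if (length(app_cols))
    vapply(app_cols, function(cc) diff(range(det[[cc]])), numeric(1)) else NULL
  for (f in frames[(frames + 1L) %in% frames]) {
    A <- det[det$frame == f, , drop = FALSE]
    B <- det[det$frame == f + 1L, , drop = FALSE]
    if (nrow(A) < 2L && nrow(B) < 2L) next  # no competition possible
    # crowding test: any other detection within gate of a receiver
    crowded <- vapply(seq_len(nrow(B)), function(j) {
      db <- sqrt((B$x_px - B$x_px[j])^2 + (B$y_px - B$y_px[j])^2)
      da <- sqrt((A$x_px - B$x_px[j])^2 + (A$y_px - B$y_px[j])^2)
      sum(db <= p$gate_px) > 1L || sum(da <= p$gate_px) > 1L
    }, logical(1))
    if (!any(crowded)) next
    res <- solve_frame_assignment(A, B, p, app_cols, app_scale,
                                  compute_margins = TRUE)
    if (!nrow(res$matches)) next
    amb <- res$matches[crowded[res$matches$j] &
                         res$matches$margin < margin_thresh, , drop = FALSE]
    if (nrow(amb))
      add("ambiguity", f + 1L, B$x_px[amb$j], B$y_px[amb$j],
          pmax(amb$margin, 0))
  }

  if (!length(cues))
    return(data.frame(cue_type = character(0), frame = integer(0),
                      x_px = numeric(0), y_px = numeric(0),
                      magnitude = numeric(0)))
  out <- do.call(rbind, cues)
  rownames(out) <- NULL
  out
}

#' Select frames for detector (re-)labelling
#'
#' Round one of training uses a uniform random sample of frames; round two
#' concentrates labelling effort on the frames with the most error cues.
#'
#' @param fs a [frame_set()].
#' @param cues cue data.frame from [extract_cues()] (used in `"hard"` mode).
#' @param n number of frames to select (`<=` number of frames).
#' @param mode `"random"` (uniform, seeded) or `"hard"` (most cues first,
#'   ties broken by earliest frame).
#' @param seed RNG seed for `"random"` mode.
#' @return integer vector of frame indices.
#' @export
select_training_frames <- function(fs, cues = NULL, n,
                                   mode = c("random", "hard"), seed = 1) {
  mode <- match.arg(mode)
  frames <- if (nrow(fs$detections)) {
    seq(min(fs$detections$frame), max(fs$detections$frame))
  } else integer(0)
  if (n > length(frames))
    stop("requested ", n, " frames but only ", length(frames), " available")
  if (n == 0L) return(integer(0))
  if (mode == "random") {
    set.seed(seed)
    return(sort(sample(frames, n)))
  }
  counts <- rep(0L, length(frames))
  if (!is.null(cues) && nrow(cues)) {
    tb <- table(factor(cues$frame, levels = frames))
    counts <- as.integer(tb)
  }
  frames[order(-counts, frames)][seq_len(n)]
}
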