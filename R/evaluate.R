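# Tracking evaluation against simulator ground truth, in the error
# vocabulary of manual video checking: fraction of error-free trajectories,
# ID switches, samples on a wrong ant or on no ant, per-ant recall.

#' Evaluate recovered trajectories against ground truth
#'
#' Each recovered sample is attributed to the nearest true ant present in
#' its frame within `match_dist_px` (or to no ant). A recovered trajectory
#' is owned by the true ant holding the majority of its real (non
#' interpolated) samples; it is error-free when every real sample lies
#' within `match_dist_px` of that one ant's true position (two coincident
#' ants both own a sample, so attributing it to the marginally nearer one
#' is not an error). An ID switch is a transition between two different
#' owning ants inside one recovered trajectory.
#'
#' @param truth a `sim_scene`, or a data.frame `ant, frame, x_px, y_px`.
#' @param recovered list of `ant_trajectory` (pixel coordinates).
#' @param match_dist_px sample-attribution distance threshold.
#' @return list of class `tracking_eval`: `n_truth`, `n_recovered`,
#'   `frac_error_free`, `id_switches`, `sample_error_rate` (fraction of
#'   real samples on a wrong/no ant), `recall` (per-ant data.frame and its
#'   mean `mean_recall`), `per_trajectory` details.
#' @export
evaluate_tracking <- function(truth, recovered, match_dist_px = 10) {
  tdf <- if (inherits(truth, "sim_scene")) truth$truth_df else truth
  stopifnot(all(c("ant", "frame", "x_px", "y_px") %in% names(tdf)))
  if (!length(recovered) || !nrow(tdf)) stop("empty truth or recovered set")

  rec <- do.call(rbind, lapply(seq_along(recovered), function(k) {
    s <- recovered[[k]]$samples
    data.frame(k = k, frame = s$frame, x_px = s$x_px, y_px = s$y_px,
               interp = s$interpolated)
  }))
  truth_by_frame <- split(tdf, tdf$frame)
  rec$owner <- NA_integer_
  for (piece in split(seq_len(nrow(rec)), rec$frame)) {
    f <- as.character(rec$frame[piece[1]])
    tf <- truth_by_frame[[f]]
    if (is.null(tf)) next
    dx <- outer(rec$x_px[piece], tf$x_px, "-")
    dy <- outer(rec$y_px[piece], tf$y_px, "-")
    dd <- sqrt(dx * dx + dy * dy)
    nearest <- max.col(-dd, ties.method = "first")
    dmin <- dd[cbind(seq_along(piece), nearest)]
    rec$owner[piece] <- ifelse(dmin <= match_dist_px, tf$ant[nearest],
                               NA_integer_)
  }

  # fast (ant, frame) -> truth position lookup
  tkey <- paste(tdf$ant, tdf$frame)
  per_traj <- do.call(rbind, lapply(seq_along(recovered), function(k) {
    idx <- which(rec$k == k & !rec$interp)
    o <- rec$owner[idx]
    maj <- if (all(is.na(o))) NA_integer_ else
      as.integer(names(which.max(table(o))))
    # a sample belongs to the majority ant when it lies within the match
    # threshold of that ant's true position; two coincident ants (e.g. a
    # merged detection) both "own" such a sample, and attributing it to
    # the marginally nearer one is not a tracking error
    if (!is.na(maj)) {
      mpos <- match(paste(maj, rec$frame[idx]), tkey)
      dmaj <- sqrt((rec$x_px[idx] - tdf$x_px[mpos])^2 +
                     (rec$y_px[idx] - tdf$y_px[mpos])^2)
      ok_sample <- !is.na(dmaj) & dmaj <= match_dist_px
    } else ok_sample <- rep(FALSE, length(idx))
    o_eff <- ifelse(ok_sample, maj, o)
    runs <- rle(o_eff[!is.na(o_eff)])$values
    data.frame(recovered_id = recovered[[k]]$ant_id, owner = maj,
               n_samples = length(o),
               n_wrong = sum(!ok_sample),
               id_switches = max(length(runs) - 1L, 0L),
               error_free = all(ok_sample),
               stringsAsFactors = FALSE)
  }))

  rec_by_frame <- split(rec[, c("x_px", "y_px")], rec$frame)
  tdf$covered <- FALSE
  for (piece in split(seq_len(nrow(tdf)), tdf$frame)) {
    rf <- rec_by_frame[[as.character(tdf$frame[piece[1]])]]
    if (is.null(rf)) next
    dx <- outer(tdf$x_px[piece], rf$x_px, "-")
    dy <- outer(tdf$y_px[piece], rf$y_px, "-")
    tdf$covered[piece] <-
      apply(sqrt(dx * dx + dy * dy), 1, min) <= match_dist_px
  }
  truth_ants <- unique(tdf$ant)
  recall <- vapply(split(tdf$covered, tdf$ant)[as.character(truth_ants)],
                   mean, numeric(1))

  structure(list(
    n_truth = length(truth_ants), n_recovered = length(recovered),
    frac_error_free = mean(per_traj$error_free),
    id_switches = sum(per_traj$id_switches),
    sample_error_rate = sum(per_traj$n_wrong) / sum(per_traj$n_samples),
    recall = data.frame(ant = truth_ants, recall = recall),
    mean_recall = mean(recall),
    per_trajectory = per_traj), class = "tracking_eval")
}

#' @export
print.tracking_eval <- function(x, ...) {
  cat(sprintf(
    paste0("<tracking_eval> %d truth ants, %d recovered trajectories\n",
           "  error-free: %.1f%%  ID switches: %d  wrong/no-ant samples: %.2f%%  mean recall: %.1f%%\n"),
    x$n_truth, x$n_recovered, 100 * x$frac_error_free, x$id_switches,
    100 * x$sample_error_rate, 100 * x$mean_recall))
  invisible(x)
}
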