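# Domain containers: trail configuration, per-frame detection sets,
# trajectories. Plain data.frame-backed S3, in the style of trajectory
# packages (adehabitatLT, trajr).

.clock_to_s <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  parts <- strsplit(as.character(x), ":", fixed = TRUE)[[1]]
  if (!length(parts) %in% 2:3 || anyNA(suppressWarnings(as.numeric(parts))))
    stop("cannot parse clock time '", x, "' (expected HH:MM[:SS])")
  p <- as.numeric(parts)
  p[1] * 3600 + p[2] * 60 + if (length(p) == 3) p[3] else 0
}

.s_to_clock <- function(s) {
  s <- round(s) %% 86400
  sprintf("%02d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, s %% 60)
}

#' Trail/camera calibration and analysis configuration
#'
#' Holds the per-video calibration (pixel size from the in-view ruler, frame
#' rate, wall-clock start time) and the geometric conventions used by the
#' trajectory filters: which axis ants cross the view along, which end of
#' that axis the nest is on, the edge margin that defines "at the view
#' boundary", and the visiting-map cell size.
#'
#' @param cm_per_px centimetres per pixel (> 0), from the in-video ruler.
#' @param fps frames per second (> 0); typical camera rates are 29.97 or 25.
#' @param start_clock wall-clock time of the first frame, `"HH:MM:SS"` or
#'   seconds since midnight. Filming runs in the evening (e.g. 19:30).
#' @param nest_side `"low"` or `"high"`: which end of the trail axis leads to
#'   the nest. Ants exiting on this side are inbound.
#' @param trail_axis `"x"` or `"y"`: the axis along which ants cross the view.
#' @param edge_margin_frac fraction of the trail-axis extent counted as "at
#'   the boundary" (in (0, 0.5)); used by the complete-crossing filter.
#' @param cell_size_cm visiting-map grid cell side in cm (default 1, i.e.
#'   roughly 1 cm^2 squares).
#' @return object of class `trail_config`.
#' @export
trail_config <- function(cm_per_px, fps = 25, start_clock = "19:30:00",
                         nest_side = "low", trail_axis = "x",
                         edge_margin_frac = 0.05, cell_size_cm = 1.0) {
  bad <- character(0)
  if (!is.numeric(cm_per_px) || length(cm_per_px) != 1 || is.na(cm_per_px) ||
      cm_per_px <= 0) bad <- c(bad, "cm_per_px")
  if (!is.numeric(fps) || length(fps) != 1 || is.na(fps) || fps <= 0)
    bad <- c(bad, "fps")
  if (!nest_side %in% c("low", "high")) bad <- c(bad, "nest_side")
  if (!trail_axis %in% c("x", "y")) bad <- c(bad, "trail_axis")
  if (!is.numeric(edge_margin_frac) || edge_margin_frac <= 0 ||
      edge_margin_frac >= 0.5) bad <- c(bad, "edge_margin_frac")
  if (!is.numeric(cell_size_cm) || cell_size_cm <= 0) bad <- c(bad, "cell_size_cm")
  start_s <- tryCatch(.clock_to_s(start_clock), error = function(e) NA_real_)
  if (is.na(start_s)) bad <- c(bad, "start_clock")
  if (length(bad))
    stop("invalid trail_config field(s): ", paste(bad, collapse = ", "))
  structure(list(cm_per_px = cm_per_px, fps = fps,
                 start_clock = start_clock, start_clock_s = start_s,
                 nest_side = nest_side, trail_axis = trail_axis,
                 edge_margin_frac = edge_margin_frac,
                 cell_size_cm = cell_size_cm),
            class = "trail_config")
}

#' Load a trail configuration from a JSON file
#'
#' Unspecified keys take the documented [trail_config()] defaults; `cm_per_px`
#' is required. Validation failures name the offending keys.
#'
#' @param path path to a JSON file with `trail_config` keys.
#' @return a `trail_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("cm_per_px", "fps", "start_clock", "nest_side", "trail_axis",
             "edge_margin_frac", "cell_size_cm")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    warning("ignoring unknown config key(s): ", paste(extra, collapse = ", "))
  if (is.null(raw$cm_per_px)) stop("config is missing required key: cm_per_px")
  do.call(trail_config, raw[intersect(names(raw), known)])
}

#' Per-frame detection set
#'
#' Groups detections (one row per detected ant instance) by frame under fixed
#' view bounds and frame rate. Frames with no detections are valid and simply
#' have no rows. Appearance descriptor columns (`a0`, `a1`, ...) are optional
#' but must be present for all detections or none.
#'
#' @param detections data.frame with columns `frame` (integer >= 0), `x_px`,
#'   `y_px`, optional `confidence` and appearance columns `a0..aK`.
#' @param view_width_px,view_height_px positive view bounds in pixels.
#' @param fps frames per second (> 0).
#' @return object of class `frame_set`.
#' @export
frame_set <- function(detections, view_width_px, view_height_px, fps) {
  stopifnot(view_width_px > 0, view_height_px > 0, fps > 0)
  need <- c("frame", "x_px", "y_px")
  miss <- setdiff(need, names(detections))
  if (length(miss)) stop("detections missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(detections)) {
    if (any(detections$frame < 0)) stop("negative frame index")
    if (any(detections$x_px < 0 | detections$x_px > view_width_px |
            detections$y_px < 0 | detections$y_px > view_height_px))
      stop("detection coordinates outside view bounds")
  }
  if (is.null(detections$confidence))
    detections$confidence <- rep(1, nrow(detections))
  app_cols <- grep("^a[0-9]+$", names(detections), value = TRUE)
  if (length(app_cols)) {
    app_cols <- app_cols[order(as.integer(sub("^a", "", app_cols)))]
    if (anyNA(detections[app_cols]))
      stop("appearance columns must be fully populated or absent")
  }
  detections$frame <- as.integer(detections$frame)
  detections <- detections[order(detections$frame), , drop = FALSE]
  rownames(detections) <- NULL
  structure(list(detections = detections,
                 view_width_px = view_width_px,
                 view_height_px = view_height_px,
                 fps = fps, app_cols = app_cols),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  nf <- length(unique(x$detections$frame))
  cat(sprintf("<frame_set> %d detections in %d frames, view %gx%g px @ %g fps\n",
              nrow(x$detections), nf, x$view_width_px, x$view_height_px, x$fps))
  invisible(x)
}

# detections of one frame (data.frame, possibly 0-row)
.dets_at <- function(fs, f) {
  fs$detections[fs$detections$frame == f, , drop = FALSE]
}

#' Read a detection CSV into a frame set
#'
#' The dialect is MOT-challenge-like but without identities: columns
#' `frame,x,y` plus optional `confidence` and appearance columns `a0..aK`,
#' one row per detection. Frames absent from the file are represented as
#' empty.
#'
#' @param path CSV path.
#' @param view numeric length-2, view width and height in pixels.
#' @param fps frames per second.
#' @return a [frame_set()].
#' @export
read_detections <- function(path, view, fps) {
  if (!file.exists(path)) stop("detection file not found: ", path)
  stopifnot(length(view) == 2, all(view > 0))
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0 && ncol(d) == 0) {
    return(frame_set(data.frame(frame = integer(0), x_px = numeric(0),
                                y_px = numeric(0)),
                     view[1], view[2], fps))
  }
  need <- c("frame", "x", "y")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("detection file missing column(s): ",
                         paste(miss, collapse = ", "))
  num_cols <- intersect(c(need, "confidence",
                          grep("^a[0-9]+$", names(d), value = TRUE)), names(d))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(d[[cc]]))
    bad <- which(is.na(v) & !is.na(d[[cc]]) | is.na(d[[cc]]))
    if (length(bad))
      stop(sprintf("malformed value in column '%s' at line %d of %s",
                   cc, bad[1] + 1L, path))  # +1 for the header line
    d[[cc]] <- v
  }
  oob <- which(d$x < 0 | d$x > view[1] | d$y < 0 | d$y > view[2])
  if (length(oob))
    stop(sprintf("coordinates outside view bounds at line %d of %s",
                 oob[1] + 1L, path))
  names(d)[match(c("x", "y"), names(d))] <- c("x_px", "y_px")
  frame_set(d, view[1], view[2], fps)
}

#' Construct a trajectory
#'
#' An identified ant's sample sequence over frames, in pixel coordinates;
#' [calibrate_trajectory()] adds seconds, wall clock and centimetres.
#'
#' @param ant_id integer identity.
#' @param samples data.frame with `frame`, `x_px`, `y_px` and logical
#'   `interpolated` (gap-bridged samples); frames strictly increasing.
#' @param view_px numeric length-2 view bounds in pixels.
#' @param complete logical: starts and ends at a trail-axis boundary.
#' @param uturn_part `"none"`, `"first"` or `"second"`.
#' @param direction `"outbound"`, `"inbound"` or `"unknown"`.
#' @param meta optional list of extra fields (e.g. simulator ground truth).
#' @return object of class `ant_trajectory`.
#' @export
ant_trajectory <- function(ant_id, samples, view_px,
                           complete = FALSE, uturn_part = "none",
                           direction = "unknown", meta = list()) {
  stopifnot(nrow(samples) >= 2, all(diff(samples$frame) > 0))
  if (is.null(samples$interpolated)) samples$interpolated <- FALSE
  stopifnot(uturn_part %in% c("none", "first", "second"),
            direction %in% c("outbound", "inbound", "unknown"))
  rownames(samples) <- NULL
  structure(list(ant_id = as.integer(ant_id), samples = samples,
                 view_px = view_px, complete = complete,
                 uturn_part = uturn_part, direction = direction, meta = meta),
            class = "ant_trajectory")
}

#' @export
print.ant_trajectory <- function(x, ...) {
  cat(sprintf(
    "<ant_trajectory %d> %d samples, frames %d-%d, %s%s%s\n",
    x$ant_id, nrow(x$samples), min(x$samples$frame), max(x$samples$frame),
    x$direction, if (x$complete) ", complete" else "",
    if (x$uturn_part != "none") paste0(", U-turn ", x$uturn_part) else ""))
  invisible(x)
}

.traj_key <- function(t) {
  if (t$uturn_part == "none") as.character(t$ant_id)
  else paste0(t$ant_id, ".", t$uturn_part)
}

#' Write trajectories and their metric records to CSV
#'
#' Emits `<prefix>_samples.csv` (long format: one row per calibrated sample)
#' and `<prefix>_metrics.csv` (one row per trajectory). Round-trips with
#' [read_trajectories()].
#'
#' @param trajs list of calibrated `ant_trajectory`.
#' @param records metrics data.frame as built by [summarize_trajectories()]
#'   (may be empty).
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_trajectories <- function(trajs, records, prefix) {
  ids <- vapply(trajs, function(t) t$ant_id, integer(1))
  if (nrow(records) && !all(records$ant_id %in% ids))
    stop("metric records reference ant_ids absent from the trajectory list")
  samp <- if (length(trajs)) {
    do.call(rbind, lapply(trajs, function(t) {
      s <- t$samples
      if (is.null(s$t_s)) stop("trajectories must be calibrated before writing")
      data.frame(ant_id = t$ant_id, uturn_part = t$uturn_part,
                 frame = s$frame, t_s = s$t_s, clock = .s_to_clock(s$clock_s),
                 x_cm = s$x_cm, y_cm = s$y_cm,
                 interpolated = s$interpolated)
    }))
  } else {
    data.frame(ant_id = integer(0), uturn_part = character(0),
               frame = integer(0), t_s = numeric(0), clock = character(0),
               x_cm = numeric(0), y_cm = numeric(0), interpolated = logical(0))
  }
  f_s <- paste0(prefix, "_samples.csv")
  f_m <- paste0(prefix, "_metrics.csv")
  write.csv(samp, f_s, row.names = FALSE)
  write.csv(records, f_m, row.names = FALSE)
  invisible(c(samples = f_s, metrics = f_m))
}

#' Read back trajectory tables written by [write_trajectories()]
#'
#' @param prefix the path prefix used when writing.
#' @return list with `samples` and `metrics` data.frames.
#' @export
read_trajectories <- function(prefix) {
  list(samples = read.csv(paste0(prefix, "_samples.csv"),
                          stringsAsFactors = FALSE),
       metrics = read.csv(paste0(prefix, "_metrics.csv"),
                          stringsAsFactors = FALSE))
}
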