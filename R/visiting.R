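# Ants Visiting Map: an occupancy grid of ~1 cm^2 cells over the trail
# view. Each trajectory is rasterized onto the grid with a supercover-style
# traversal (no skipped cells however fast the ant), and cells are counted
# either by distinct trajectories or by entry events. The exploration index
# of a trajectory scores how unusual its cells are.

# grid traversal of one segment (cm coordinates, cell size cs): returns the
# cells visited *after* the starting cell as a 2-column matrix (col, row),
# 0-based. Amanatides-Woo DDA; exact corner hits step x first, so the path
# is always edge/corner connected.
.raster_segment <- function(x0, y0, x1, y1, cs) {
  cx <- floor(x0 / cs); cy <- floor(y0 / cs)
  ex <- floor(x1 / cs); ey <- floor(y1 / cs)
  nstep <- abs(ex - cx) + abs(ey - cy)
  if (nstep == 0L) return(NULL)
  out <- matrix(0L, nstep, 2)
  dx <- x1 - x0; dy <- y1 - y0
  sx <- sign(dx); sy <- sign(dy)
  tmx <- if (sx > 0) ((cx + 1) * cs - x0) / dx else if (sx < 0)
    (cx * cs - x0) / dx else Inf
  tmy <- if (sy > 0) ((cy + 1) * cs - y0) / dy else if (sy < 0)
    (cy * cs - y0) / dy else Inf
  tdx <- if (sx != 0) cs / abs(dx) else Inf
  tdy <- if (sy != 0) cs / abs(dy) else Inf
  for (k in seq_len(nstep)) {
    if (tmx <= tmy) { cx <- cx + sx; tmx <- tmx + tdx }
    else            { cy <- cy + sy; tmy <- tmy + tdy }
    out[k, 1] <- cx; out[k, 2] <- cy
  }
  out
}

# ordered cell-id path of a trajectory (consecutive duplicates collapsed).
# Cells are half-open squares [k*cs, (k+1)*cs); ids are 0-based
# row * n_cols + col. Coordinates are clamped into the grid so a point on
# the far view boundary belongs to the last cell.
.cell_path <- function(x, y, cs, n_cols, n_rows) {
  eps <- 1e-9
  x <- pmin(pmax(x, 0), n_cols * cs - eps)
  y <- pmin(pmax(y, 0), n_rows * cs - eps)
  cx <- floor(x / cs); cy <- floor(y / cs)
  path_c <- cx[1]; path_r <- cy[1]
  if (length(x) > 1) {
    moved <- which(diff(cx) != 0 | diff(cy) != 0)
    segs <- vector("list", length(moved) + 1L)
    segs[[1]] <- cbind(path_c, path_r)
    for (si in seq_along(moved)) {
      i <- moved[si]
      segs[[si + 1L]] <- .raster_segment(x[i], y[i], x[i + 1], y[i + 1], cs)
    }
    cells <- do.call(rbind, segs)
    path_c <- cells[, 1]; path_r <- cells[, 2]
  }
  path_c <- pmin(pmax(path_c, 0L), n_cols - 1L)
  path_r <- pmin(pmax(path_r, 0L), n_rows - 1L)
  ids <- path_r * n_cols + path_c
  if (length(ids) > 1) ids <- ids[c(TRUE, diff(ids) != 0)]
  ids
}

#' Ants Visiting Map
#'
#' Divides the trail view into square cells of side `cell_size_cm`
#' (~1 cm^2 by default) and counts, per cell, either how many distinct
#' trajectories traverse it (`mode = "trajectories"`, used for the
#' exploration index) or how many times an ant walks into it
#' (`mode = "entries"`, re-entries counted; the first cell of a trajectory
#' counts as one entry). Segments are rasterized with a supercover
#' traversal so fast ants skip no cells.
#'
#' @param trajs list of calibrated `ant_trajectory`.
#' @param cfg a [trail_config()].
#' @param mode `"trajectories"` or `"entries"`.
#' @return object of class `visiting_map`: counts matrix (`n_rows` x
#'   `n_cols`), cell size, mode, `V_max` (max count over visited cells) and
#'   the per-trajectory distinct cell sets keyed by trajectory.
#' @export
visiting_map <- function(trajs, cfg, mode = c("trajectories", "entries")) {
  mode <- match.arg(mode)
  if (!length(trajs)) stop("no trajectories")
  if (is.null(trajs[[1]]$samples$x_cm)) stop("trajectories are not calibrated")
  cs <- cfg$cell_size_cm
  view_px <- trajs[[1]]$view_px
  n_cols <- max(1L, ceiling(view_px[1] * cfg$cm_per_px / cs))
  n_rows <- max(1L, ceiling(view_px[2] * cfg$cm_per_px / cs))
  counts <- matrix(0L, n_rows, n_cols)
  cell_sets <- list()
  for (t in trajs) {
    ids <- .cell_path(t$samples$x_cm, t$samples$y_cm, cs, n_cols, n_rows)
    uniq <- unique(ids)
    cell_sets[[.traj_key(t)]] <- uniq
    if (mode == "trajectories") {
      counts[uniq + 1L] <- counts[uniq + 1L] + 1L
    } else {
      tb <- table(ids)
      idx <- as.integer(names(tb)) + 1L
      counts[idx] <- counts[idx] + as.integer(tb)
    }
  }
  structure(list(counts = counts, cell_size_cm = cs, n_cols = n_cols,
                 n_rows = n_rows, mode = mode,
                 V_max = if (any(counts > 0)) max(counts) else 0L,
                 n_trajs = length(trajs), cell_sets = cell_sets),
            class = "visiting_map")
}

#' @export
print.visiting_map <- function(x, ...) {
  cat(sprintf("<visiting_map> %dx%d cells of %g cm, mode=%s, V_max=%d, %d trajectories\n",
              x$n_rows, x$n_cols, x$cell_size_cm, x$mode, x$V_max, x$n_trajs))
  invisible(x)
}

#' Exploration index of a trajectory
#'
#' Scores each visited cell by how unusual it is among the mapped
#' trajectories: `s(c) = (V_max - V(c)) / (V_max - 1)` when `V_max > 1`,
#' else 1 (a sole trajectory is maximally exploratory). The exploration
#' index `EI` is the sum of scores over the distinct cells the trajectory
#' traverses; the average exploration index `AEI = EI / #cells` normalizes
#' for trajectory length and lies in \[0, 1\]: 1 when every cell is visited
#' by this trajectory alone, 0 when every cell is maximally shared.
#'
#' @param t a calibrated `ant_trajectory` that was part of the map.
#' @param vm a trajectories-mode [visiting_map()].
#' @return named numeric `c(EI, AEI)`.
#' @export
exploration_index <- function(t, vm) {
  if (vm$mode != "trajectories")
    stop("exploration_index needs a trajectories-mode visiting map")
  ids <- vm$cell_sets[[.traj_key(t)]]
  if (is.null(ids))
    ids <- unique(.cell_path(t$samples$x_cm, t$samples$y_cm,
                             vm$cell_size_cm, vm$n_cols, vm$n_rows))
  if (!length(ids)) stop("trajectory traverses zero cells")
  V <- vm$counts[ids + 1L]
  s <- if (vm$V_max > 1) (vm$V_max - V) / (vm$V_max - 1) else rep(1, length(V))
  c(EI = sum(s), AEI = sum(s) / length(s))
}

# monotone grey ramp: darker = more visited (0 visits = white)
.heatmap_grey <- function(counts, v_max = max(counts, 1)) {
  1 - 0.9 * pmin(counts, v_max) / max(v_max, 1)
}

#' Export a visiting map as CSV and image
#'
#' Writes the count grid as `<prefix>.csv` (rows = grid rows), an ASCII
#' PGM greyscale image `<prefix>.pgm` (darker cells were walked over more;
#' the scale is per-map, as each night uses its own scale), and, when the
#' running R has PNG capability, `<prefix>.png`.
#'
#' @param vm a [visiting_map()].
#' @param prefix output path prefix.
#' @return invisibly, the written file paths.
#' @export
export_heatmap <- function(vm, prefix) {
  f_csv <- paste0(prefix, ".csv")
  write.table(vm$counts, f_csv, sep = ",", row.names = FALSE,
              col.names = FALSE)
  grey_lv <- .heatmap_grey(vm$counts)
  f_pgm <- paste0(prefix, ".pgm")
  con <- file(f_pgm, "w")
  writeLines(c("P2", paste(vm$n_cols, vm$n_rows), "255"), con)
  write(t(round(grey_lv * 255)), con, ncolumns = vm$n_cols)
  close(con)
  paths <- c(csv = f_csv, pgm = f_pgm)
  if (isTRUE(unname(capabilities("png")))) {
    f_png <- paste0(prefix, ".png")
    grDevices::png(f_png, width = 40 * vm$n_cols, height = 40 * vm$n_rows)
    op <- par(mar = c(0, 0, 0, 0))
    image(t(grey_lv[vm$n_rows:1, , drop = FALSE]), col = gray(seq(0, 1, length.out = 256)),
          zlim = c(0, 1), axes = FALSE, useRaster = TRUE)
    par(op)
    grDevices::dev.off()
    paths <- c(paths, png = f_png)
  }
  invisible(paths)
}
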