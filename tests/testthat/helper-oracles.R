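# Independent oracles and fixture builders shared across the suite.

# Brute-force minimum-cost partial matching: every supplier either matches
# an unused feasible receiver or dies; unmatched detections cost `bdc`.
# Exhaustive recursion, usable up to ~6x6.
brute_force_assignment <- function(C, bdc) {
  n <- nrow(C); m <- ncol(C)
  best <- Inf
  rec <- function(i, used, acc) {
    if (acc >= best) return(invisible())
    if (i > n) {
      tot <- acc + bdc * (m - sum(used))
      if (tot < best) best <<- tot
      return(invisible())
    }
    rec(i + 1L, used, acc + bdc)
    for (j in seq_len(m)) {
      if (!used[j] && C[i, j] < 1e7) {
        u <- used; u[j] <- TRUE
        rec(i + 1L, u, acc + C[i, j])
      }
    }
  }
  rec(1L, rep(FALSE, m), 0)
  best
}

# random gated instance for solver fuzzing; returns detection tables
random_instance <- function(n, m, gate = 30) {
  A <- data.frame(x_px = runif(n, 0, 100), y_px = runif(n, 0, 100))
  B <- data.frame(x_px = runif(m, 0, 100), y_px = runif(m, 0, 100))
  list(A = A, B = B)
}

# trajectory fixture from cm coordinates (already "calibrated"); fps 1 so
# t_s = frame, cm_per_px 1 so px = cm
traj_cm <- function(x, y, ant_id = 1L, frame = seq_along(x) - 1L,
                    view_cm = c(15, 4), fps = 25) {
  s <- data.frame(frame = frame, x_px = x, y_px = y, interpolated = FALSE)
  t <- ant_trajectory(ant_id, s, view_px = view_cm)
  calibrate_trajectory(t, trail_config(cm_per_px = 1, fps = fps))
}

test_cfg <- function(...) trail_config(cm_per_px = 1, fps = 25, ...)

# straight detection track in px: one ant moving along +x
straight_track <- function(x0, y0, vx, n_frames, f0 = 0L, vy = 0) {
  data.frame(frame = f0 + seq_len(n_frames) - 1L,
             x = x0 + vx * (seq_len(n_frames) - 1L),
             y = y0 + vy * (seq_len(n_frames) - 1L))
}

# write a detection CSV and read it back as a frame_set
as_frameset <- function(det, view = c(600, 400), fps = 25) {
  f <- tempfile(fileext = ".csv")
  write.csv(det, f, row.names = FALSE)
  on.exit(unlink(f))
  read_detections(f, view, fps)
}

# method-of-moments beta parameter oracle (independent of the EM path)
beta_mom_oracle <- function(x) {
  m <- mean(x); v <- var(x)
  phi <- m * (1 - m) / v - 1
  c(mu = m, phi = phi)
}
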