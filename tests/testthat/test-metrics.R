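test_that("path length, displacement, straightness: closed-form fixtures", {
  t345 <- traj_cm(c(0, 3, 3), c(0, 0, 4))
  ld <- path_length_and_displacement(t345)
  expect_equal(unname(ld), c(7, 5))
  expect_equal(straightness(t345), 5 / 7)

  line <- traj_cm(c(0, 2, 5, 9), c(0, 2, 5, 9))
  expect_equal(straightness(line), 1)

  loop <- traj_cm(c(0, 3, 3, 0), c(0, 0, 3, 0))
  expect_equal(straightness(loop), 0)

  two <- traj_cm(c(0, 10), c(0, 0))
  ld2 <- path_length_and_displacement(two)
  expect_equal(ld2[["L_cm"]], ld2[["d_cm"]])

  stationary <- traj_cm(c(1, 1), c(1, 1))
  expect_message(st <- straightness(stationary), "stationary")
  expect_true(is.na(st))
  expect_error(path_length_and_displacement(
    traj_cm(c(0, 1), c(0, 0))$samples), "calibrated")
})

test_that("average speed is path length over duration", {
  # 10 cm in 2 s at 25 fps -> 50 frames
  t <- traj_cm(c(0, 5, 10), c(0, 0, 0), frame = c(0L, 25L, 50L))
  expect_equal(average_speed(t), 5)
  # L = 7 cm (3-4-5 path) crossed in 1.4 s
  t2 <- traj_cm(c(0, 3, 3), c(0, 0, 4), frame = c(0L, 15L, 35L))
  expect_equal(average_speed(t2), 5)
  t3 <- traj_cm(c(0, 1), c(0, 0), frame = c(0L, 1L))
  t3$samples$t_s <- c(0, 0)
  expect_error(average_speed(t3), "duration")
})

test_that("visiting map counts distinct trajectories vs entry events", {
  cfg <- test_cfg()
  straight <- traj_cm(seq(0.5, 14.5, length.out = 30), rep(2.5, 30))
  vm <- visiting_map(list(straight), cfg, mode = "trajectories")
  expect_equal(sum(vm$counts == 1), 15)   # one row of 15 cells
  expect_equal(sum(vm$counts), 15)
  vme <- visiting_map(list(straight), cfg, mode = "entries")
  expect_equal(vme$counts, vm$counts)     # no re-entries on a straight pass

  dup <- straight; dup$ant_id <- 2L
  vm2 <- visiting_map(list(straight, dup), cfg, mode = "trajectories")
  expect_equal(sum(vm2$counts == 2), 15)
  expect_equal(vm2$V_max, 2)

  # oscillating between two cells 3 times: entries 3+3, trajectories 1+1
  osc <- traj_cm(c(0.5, 1.5, 0.5, 1.5, 0.5, 1.5), rep(0.5, 6))
  vme2 <- visiting_map(list(osc), cfg, mode = "entries")
  expect_equal(sort(vme2$counts[vme2$counts > 0]), c(3, 3))
  vmt2 <- visiting_map(list(osc), cfg, mode = "trajectories")
  expect_equal(sort(vmt2$counts[vmt2$counts > 0]), c(1, 1))
})

test_that("entries total equals entry events; counts bounded by trajectory count", {
  set.seed(9)
  cfg <- test_cfg()
  trajs <- lapply(1:6, function(i)
    traj_cm(cumsum(c(runif(1, 0, 3), runif(25, -0.4, 1))),
            pmin(pmax(cumsum(c(2, runif(25, -0.5, 0.5))), 0.05), 3.95),
            ant_id = i))
  vmt <- visiting_map(trajs, cfg, mode = "trajectories")
  expect_lte(max(vmt$counts), 6)
  vme <- visiting_map(trajs, cfg, mode = "entries")
  entry_events <- sum(vapply(trajs, function(t) {
    ids <- trailtrack:::.cell_path(t$samples$x_cm, t$samples$y_cm, 1,
                                   vmt$n_cols, vmt$n_rows)
    length(ids)
  }, numeric(1)))
  expect_equal(sum(vme$counts), entry_events)
})

test_that("supercover traversal yields connected cell paths with no skips", {
  set.seed(13)
  for (rep in 1:200) {
    x <- runif(2, 0, 15); y <- runif(2, 0, 4)
    ids <- trailtrack:::.cell_path(x, y, 1, 15, 4)
    cols <- ids %% 15; rows <- ids %/% 15
    if (length(ids) > 1) {
      dc <- abs(diff(cols)); dr <- abs(diff(rows))
      expect_true(all(pmax(dc, dr) == 1))  # each move to an adjacent cell
    }
    # endpoints' cells are on the path
    expect_true(floor(min(x, 14.999)) %in% cols |
                  length(unique(cols)) == 1)
  }
  # a fast diagonal ant (one sample per 5 cells) still covers every cell
  ids <- trailtrack:::.cell_path(c(0.5, 14.5), c(0.5, 3.5), 1, 15, 4)
  expect_gte(length(ids), 15)
})

test_that("exploration index: sole, duplicated, and mixed-share fixtures", {
  cfg <- test_cfg()
  solo <- traj_cm(seq(0.5, 14.5, length.out = 30), rep(2.5, 30))
  vm1 <- visiting_map(list(solo), cfg)
  ei <- exploration_index(solo, vm1)
  expect_equal(ei[["AEI"]], 1)   # V_max = 1 branch

  dup <- solo; dup$ant_id <- 2L
  vm2 <- visiting_map(list(solo, dup), cfg)
  expect_equal(exploration_index(solo, vm2)[["AEI"]], 0)
  expect_equal(exploration_index(dup, vm2)[["AEI"]], 0)

  # 3 trajectories; A traverses 10 cells: 5 shared by all, 5 unique
  A <- traj_cm(seq(0.5, 9.5, length.out = 20), rep(0.5, 20), ant_id = 1L)
  B <- traj_cm(seq(0.5, 4.5, length.out = 10), rep(0.5, 10), ant_id = 2L)
  C <- traj_cm(seq(0.5, 4.5, length.out = 10), rep(0.5, 10), ant_id = 3L)
  vm3 <- visiting_map(list(A, B, C), cfg)
  eiA <- exploration_index(A, vm3)
  expect_equal(eiA[["EI"]], 5)     # 5 * 0 + 5 * 1
  expect_equal(eiA[["AEI"]], 0.5)
})

test_that("removing a trajectory never decreases others' exploration", {
  set.seed(31)
  cfg <- test_cfg()
  sc <- simulate_scene(sim_params(arrival = "fixed", n_ants = 12,
                                  duration_s = 60, seed = 31))
  trajs <- calibrate_trajectories(sc$truth, cfg)
  vm_all <- visiting_map(trajs, cfg)
  vm_less <- visiting_map(trajs[-1], cfg)
  for (t in trajs[-1]) {
    expect_gte(exploration_index(t, vm_less)[["AEI"]],
               exploration_index(t, vm_all)[["AEI"]] - 1e-12)
  }
})

test_that("heatmap export: CSV grid, monotone grey PGM", {
  cfg <- test_cfg()
  tr <- traj_cm(c(0.5, 1.5, 1.5, 0.5, 0.5, 1.5), c(0.5, 0.5, 1.5, 1.5, 0.5, 0.5))
  vm <- visiting_map(list(tr), cfg, mode = "entries")
  prefix <- tempfile()
  paths <- export_heatmap(vm, prefix)
  on.exit(unlink(paths))
  grid <- as.matrix(read.csv(paths[["csv"]], header = FALSE))
  expect_equal(unname(grid), unname(vm$counts), ignore_attr = TRUE)

  pgm <- readLines(paths[["pgm"]])
  expect_equal(pgm[1], "P2")
  vals <- scan(text = paste(pgm[-(1:3)], collapse = " "), quiet = TRUE)
  expect_length(vals, vm$n_cols * vm$n_rows)
  # intensity monotone nonincreasing in the visit count
  px <- matrix(vals, vm$n_rows, vm$n_cols, byrow = TRUE)
  o <- order(vm$counts)
  expect_true(all(diff(px[o]) <= 0 | diff(vm$counts[o]) > 0))
  expect_true(all(px[vm$counts == max(vm$counts)] <=
                    px[vm$counts == min(vm$counts)]))

  # all-zero map still exports a valid uniform image
  vm0 <- vm; vm0$counts[] <- 0L; vm0$V_max <- 0L
  p0 <- export_heatmap(vm0, tempfile())
  v0 <- scan(text = paste(readLines(p0[["pgm"]])[-(1:3)], collapse = " "),
             quiet = TRUE)
  expect_equal(unique(v0), 255)
})

test_that("summarize_trajectories assembles the full metric record", {
  cfg <- test_cfg()
  tr1 <- traj_cm(c(0.2, 7, 14.8), c(2, 2, 2), ant_id = 1L,
                 frame = c(0L, 35L, 70L))
  tr1$complete <- TRUE; tr1$direction <- "outbound"
  tr2 <- traj_cm(c(14.8, 7, 0.2), c(1, 1.5, 1), ant_id = 2L,
                 frame = c(10L, 45L, 80L))
  tr2$direction <- "inbound"
  rec <- summarize_trajectories(list(tr1, tr2), cfg)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$ST[1], 1)
  expect_true(all(rec$AEI >= 0 & rec$AEI <= 1))
  expect_equal(rec$direction, c("outbound", "inbound"))
  expect_equal(rec$mean_speed_cm_s[1], 14.6 / 2.8)
  # stationary trajectories are excluded with a reason
  st <- traj_cm(c(5, 5, 5), c(2, 2, 2), ant_id = 3L)
  rec2 <- suppressMessages(summarize_trajectories(list(tr1, st), cfg))
  expect_equal(nrow(rec2), 1)
  expect_equal(attr(rec2, "excluded")$reason, "stationary")
})
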