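test_that("scenes are seed-deterministic and respect stated limits", {
  p <- sim_params(arrival = "fixed", n_ants = 15, duration_s = 60, seed = 21)
  s1 <- simulate_scene(p)
  s2 <- simulate_scene(p)
  expect_identical(s1$detections, s2$detections)
  expect_identical(s1$truth_df, s2$truth_df)

  # clean detections correspond 1-1 to ground-truth samples
  expect_equal(nrow(s1$detections),
               sum(vapply(s1$truth, function(t) nrow(t$samples), integer(1))))
  # all within view
  vw <- s1$fs_clean$view_width_px; vh <- s1$fs_clean$view_height_px
  expect_true(all(s1$detections$x_px >= 0 & s1$detections$x_px <= vw))
  expect_true(all(s1$detections$y_px >= 0 & s1$detections$y_px <= vh))
})

test_that("noiseless-heading ants walk perfectly straight", {
  p <- sim_params(arrival = "fixed", n_ants = 8, duration_s = 40,
                  group_weights = 1, group_st = 1, uturn_prob = 0,
                  seed = 22)
  sc <- simulate_scene(p)
  cfg <- sc$config
  st <- vapply(calibrate_trajectories(sc$truth, cfg), straightness,
               numeric(1))
  expect_equal(st, rep(1, length(st)))
})

test_that("uturn_prob = 1 makes every ant exit where it entered", {
  p <- sim_params(arrival = "fixed", n_ants = 12, duration_s = 80,
                  uturn_prob = 1, seed = 23)
  sc <- simulate_scene(p)
  for (t in sc$truth) {
    x <- t$samples$x_px
    w <- t$view_px[1]
    ends <- c(x[1], x[length(x)])
    expect_true(all(ends < w / 2) || all(ends > w / 2))
    expect_true(t$meta$uturn)
  }
})

test_that("realized speeds and straightness track the configured targets", {
  p <- sim_params(arrival = "fixed", n_ants = 150, duration_s = 600,
                  uturn_prob = 0, seed = 24)
  sc <- simulate_scene(p)
  cfg <- sc$config
  trajs <- calibrate_trajectories(sc$truth, cfg)
  sp <- vapply(trajs, average_speed, numeric(1))
  tv <- vapply(sc$truth, function(t) t$meta$speed_cm_s, numeric(1))
  # per-ant realized speed equals its drawn ground-truth speed
  expect_equal(sp, tv, tolerance = 0.02)
  # sample mean near the configured truncated normal mean (LLN, 3 se)
  expect_lt(abs(mean(tv) - 5.15), 3 * 1.63 / sqrt(length(tv)) + 0.05)

  # ST decreases as heading noise grows (kappa decreases)
  st_by_group <- vapply(1:4, function(g) {
    idx <- vapply(sc$truth, function(t) t$meta$group == g, logical(1))
    median(vapply(trajs[idx], straightness, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(st_by_group) < 0))
  # and centres near the group targets
  expect_equal(st_by_group, c(0.94, 0.88, 0.77, 0.49), tolerance = 0.12)
})

test_that("corruption model: identity, total loss, calibrated FP rate, merging", {
  p <- sim_params(arrival = "fixed", n_ants = 10, duration_s = 50, seed = 25)
  sc <- simulate_scene(p)
  clean <- corrupt_detections(sc, noise_params(jitter_px = 0, miss_rate = 0,
                                               fp_rate = 0,
                                               merge_dist_px = 0))
  expect_equal(nrow(clean$detections), nrow(sc$detections))
  expect_equal(sort(clean$detections$x_px), sort(sc$detections$x_px))

  gone <- corrupt_detections(sc, noise_params(miss_rate = 1, fp_rate = 0,
                                              jitter_px = 0))
  expect_equal(nrow(gone$detections), 0)

  # FP count concentrates at fp_rate * n_frames over seeds
  nfr <- max(sc$detections$frame) + 1
  fp_counts <- vapply(1:30, function(s) {
    fs <- corrupt_detections(sc, noise_params(jitter_px = 0, miss_rate = 0,
                                              fp_rate = 0.2,
                                              merge_dist_px = 0), seed = s)
    nrow(fs$detections) - nrow(sc$detections)
  }, numeric(1))
  lambda <- 0.2 * nfr
  expect_lt(abs(mean(fp_counts) - lambda), 4 * sqrt(lambda / 30))

  # two detections 3 px apart merge to their midpoint
  sc2 <- sc
  sc2$detections <- data.frame(frame = c(0L, 0L), x_px = c(100, 103),
                               y_px = c(50, 50))
  merged <- corrupt_detections(sc2, noise_params(jitter_px = 0, miss_rate = 0,
                                                 fp_rate = 0,
                                                 merge_dist_px = 6))
  expect_equal(nrow(merged$detections), 1)
  expect_equal(merged$detections$x_px, 101.5)
})

test_that("tracking evaluation scores identity and constructed failures", {
  p <- sim_params(arrival = "fixed", n_ants = 6, duration_s = 40, seed = 26)
  sc <- simulate_scene(p)
  ev <- evaluate_tracking(sc, sc$truth)
  expect_equal(ev$frac_error_free, 1)
  expect_equal(ev$id_switches, 0)
  expect_equal(ev$sample_error_rate, 0)
  expect_equal(ev$mean_recall, 1)

  # concatenating two different ants into one recovered id: 1 switch
  t1 <- sc$truth[[1]]; t2 <- sc$truth[[2]]
  s2 <- t2$samples
  s2$frame <- s2$frame + max(t1$samples$frame) - min(s2$frame) + 1L
  tdf <- sc$truth_df
  extra <- tdf[tdf$ant == 2, ]
  extra$frame <- s2$frame
  frank <- ant_trajectory(99L, rbind(t1$samples, s2), t1$view_px)
  ev2 <- evaluate_tracking(rbind(tdf[tdf$ant != 2, ], extra), list(frank))
  expect_equal(ev2$id_switches, 1)
  expect_equal(ev2$frac_error_free, 0)

  # an interpolation-only deviation is not a wrong/no-ant sample
  t3 <- sc$truth[[3]]
  s3 <- t3$samples
  mid <- ceiling(nrow(s3) / 2)
  s3$x_px[mid] <- pmin(s3$x_px[mid] + 50, t3$view_px[1])
  s3$interpolated[mid] <- TRUE
  ev3 <- evaluate_tracking(sc, list(ant_trajectory(1L, s3, t3$view_px)))
  expect_equal(ev3$sample_error_rate, 0)
  expect_equal(ev3$frac_error_free, 1)
})
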