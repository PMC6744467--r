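# The paper-reported 4-group straightness mixture used as a simulation
# truth in several tests (weights %, component means); dispersions are the
# package's documented simulation defaults.
ST_MIX <- list(w = c(0.370, 0.262, 0.300, 0.068),
               mu = c(0.94, 0.88, 0.77, 0.49),
               phi = c(600, 600, 200, 30))

rmix <- function(n, mix = ST_MIX) {
  k <- sample(seq_along(mix$w), n, replace = TRUE, prob = mix$w)
  rbeta(n, mix$mu[k] * mix$phi[k], (1 - mix$mu[k]) * mix$phi[k])
}

test_that("single-component fit matches the method-of-moments oracle", {
  set.seed(101)
  x <- rbeta(4000, 20, 5)  # mu = 0.8
  fit <- fit_beta_mixture(x, K = 1, seed = 1, restarts = 3)
  mom <- beta_mom_oracle(x)
  expect_equal(fit$mu, mom[["mu"]], tolerance = 0.02)
  expect_equal(fit$mu, 0.8, tolerance = 0.02)
  expect_equal(fit$phi, mom[["phi"]], tolerance = 0.15 * mom[["phi"]])
  expect_equal(fit$weights, 1)
  # BIC formula is exact given logL, p, n
  expect_equal(fit$BIC, -2 * fit$logL + 2 * log(length(x)))
})

test_that("EM log-likelihood is nondecreasing", {
  set.seed(102)
  x <- rmix(1500)
  fit <- fit_beta_mixture(x, K = 3, seed = 2, restarts = 2)
  expect_true(all(diff(fit$logL_trace) > -1e-6))
})

test_that("well-separated two-component mixture is recovered", {
  set.seed(103)
  k <- rbinom(5000, 1, 0.4)
  x <- ifelse(k == 1, rbeta(5000, 0.2 * 50, 0.8 * 50),
              rbeta(5000, 0.9 * 50, 0.1 * 50))
  fit <- fit_beta_mixture(x, K = 2, seed = 3)
  ord <- order(fit$mu)
  expect_equal(fit$mu[ord], c(0.2, 0.9), tolerance = 0.02)
  expect_equal(fit$weights[ord], c(0.4, 0.6), tolerance = 0.03)
})

test_that("fit preconditions and degenerate inputs error cleanly", {
  expect_error(fit_beta_mixture(runif(25), K = 3), "10\\*K")
  expect_error(fit_beta_mixture(runif(50), K = 0), "K")
  # boundary values are clamped, not fatal
  x <- c(rep(1, 30), rbeta(170, 5, 2))
  expect_s3_class(fit_beta_mixture(x, K = 1, restarts = 2), "mixture_fit")
})

test_that("BIC selects parsimonious K on single-component data and small n", {
  set.seed(104)
  x <- rbeta(3000, 15, 4)
  sel <- select_k_bic(x, K_max = 4, seed = 5, restarts = 4)
  expect_equal(sel$K_best, 1)

  xs <- rbeta(50, 5, 3)
  expect_warning(sel2 <- select_k_bic(xs, K_max = 6, seed = 5, restarts = 3),
                 "K_max reduced")
  expect_lte(sel2$K_best, 3)
})

test_that("group classification orders, names, and summarizes components", {
  set.seed(105)
  x <- rmix(8000)
  fit <- fit_beta_mixture(x, K = 4, seed = 6)
  grp <- classify_groups(fit)
  expect_equal(grp$group_names,
               c("straight", "semi-straight", "semi-curvy", "curvy"))
  expect_equal(sum(grp$summary$proportion), 1)
  expect_equal(sum(grp$summary$n), fit$n)
  # component means decrease down the table
  expect_true(all(diff(grp$summary$mean_component) < 0))
  # an observation at a component mean lands in that component
  probe_idx <- which.min(abs(x - 0.49))
  expect_equal(grp$labels[probe_idx], 4L)
  # curviest group proportion near the simulated 6.8%
  expect_equal(grp$summary$proportion[4], 0.068, tolerance = 0.035)
  # minimum observed value is reported per group (semi-curvy cutoff style)
  expect_true(all(grp$summary$min_members <= grp$summary$mean_members))
})

test_that("LMM recovers a known slope and its grouping structure", {
  set.seed(106)
  n <- 2000
  colony <- sample(paste0("MP", 1:4), n, replace = TRUE)
  date <- sample(paste0("jan", 11:14), n, replace = TRUE)
  u_c <- setNames(rnorm(4, 0, 0.3), paste0("MP", 1:4))
  u_d <- setNames(rnorm(4, 0, 0.3), paste0("jan", 11:14))
  tm <- runif(n)
  speed <- 5.6 - 0.45 * tm + u_c[colony] + u_d[date] + rnorm(n, 0, 1.5)
  d <- data.frame(speed = speed, time = tm, colony = colony, date = date)
  fit <- fit_lmm(d, "speed", "time", c("colony", "date"))
  sl <- fit$coefficients[fit$coefficients$term == "time", ]
  expect_lt(abs(sl$estimate - (-0.45)), 2 * sl$se)
  expect_true(all(fit$coefficients$se > 0))
  expect_equal(nrow(fit$diagnostics), n)
  expect_error(fit_lmm(d, "speed", "time", c("colony", "nonexistent")),
               "missing column")
  d1 <- d; d1$colony <- "MP1"
  expect_error(fit_lmm(d1, "speed", "time", c("colony", "date")),
               "fewer than 2 levels")
})

test_that("LMM slope is null-calibrated and sign-faithful", {
  set.seed(107)
  # null: no time effect; p should not be systematically small
  pvals <- replicate(25, {
    n <- 300
    d <- data.frame(speed = rnorm(n, 5, 1.5), time = runif(n),
                    colony = sample(letters[1:4], n, TRUE),
                    date = sample(letters[5:8], n, TRUE))
    f <- suppressMessages(fit_lmm(d, "speed", "time", c("colony", "date")))
    f$coefficients$p[f$coefficients$term == "time"]
  })
  expect_lte(sum(pvals < 0.05), 5)  # ~1.25 expected at the 5% level
  expect_gt(mean(pvals), 0.25)

  # AEI declining in ST gives a negative coefficient
  n <- 1500
  st <- rbeta(n, 8, 2)
  d2 <- data.frame(AEI = pmin(pmax(0.35 - 0.11 * st +
                                     rnorm(n, 0, 0.08), 0), 1),
                   ST = st,
                   colony = sample(letters[1:4], n, TRUE),
                   date = sample(letters[5:8], n, TRUE))
  f2 <- suppressMessages(fit_lmm(d2, "AEI", "ST", c("colony", "date")))
  expect_lt(f2$coefficients$estimate[f2$coefficients$term == "ST"], 0)
})

test_that("interval comparison bins half-hours and adjusts pairwise tests", {
  set.seed(108)
  # records spanning 19:30-00:00 -> 9 intervals
  n <- 900
  clock_s <- 19.5 * 3600 + runif(n, 0, 4.5 * 3600 - 1)
  iv <- floor(clock_s / 1800) * 1800
  first <- iv == min(iv)
  d <- data.frame(clock_s = clock_s,
                  AEI = pmin(pmax(0.15 + 0.12 * first + rnorm(n, 0, 0.1), 0), 1),
                  colony = sample(letters[1:4], n, TRUE),
                  date = sample(letters[5:8], n, TRUE))
  res <- suppressMessages(interval_comparison(d))
  expect_length(res$intervals, 9)
  expect_equal(res$intervals[1], "19:30:00")
  expect_equal(nrow(res$contrasts), choose(9, 2))
  expect_true(all(res$contrasts$p_tukey >= 0 & res$contrasts$p_tukey <= 1))
  # the elevated first interval separates from the others
  c1 <- res$contrasts[grepl("^19:30:00", res$contrasts$contrast), ]
  expect_true(all(c1$p_tukey < 0.01))
  expect_gt(res$means$estimate[1], max(res$means$estimate[-1]))

  # sparse interval is dropped with a warning
  d2 <- rbind(d, data.frame(clock_s = 86400 + 3600, AEI = 0.2,
                            colony = "a", date = "e"))
  expect_warning(interval_comparison(d2), "dropping interval")
})

test_that("Tukey family-wise error stays near nominal under the null", {
  set.seed(109)
  any_sig <- replicate(30, {
    n <- 240
    d <- data.frame(clock_s = 19.5 * 3600 + runif(n, 0, 4.5 * 3600 - 1),
                    AEI = rnorm(n, 0.2, 0.1),
                    colony = sample(letters[1:3], n, TRUE),
                    date = sample(letters[4:6], n, TRUE))
    r <- suppressMessages(interval_comparison(d))
    any(r$contrasts$p_tukey < 0.05)
  })
  # 30 null replicates at FWER 0.05: P(>5 hits) < 1%
  expect_lte(sum(any_sig), 5)
})
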