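test_that("gravity rotation behaves as a planar isometry", {
  g <- matrix(c(100, 0, 5), 1)
  expect_equal(rotate_grf_to_gravity(g, 0), g)

  # pure belt-normal force on a 6 degree slope splits as (F cos, F sin)
  out <- rotate_grf_to_gravity(matrix(c(100, 0, 0), 1), 6)
  expect_equal(out[1], 100 * cos(6 * pi / 180))
  expect_equal(out[2], 100 * sin(6 * pi / 180))

  set.seed(1)
  r <- matrix(rnorm(300), ncol = 3)
  rot <- rotate_grf_to_gravity(r, -8.3)
  n0 <- sqrt(r[, 1]^2 + r[, 2]^2)
  n1 <- sqrt(rot[, 1]^2 + rot[, 2]^2)
  expect_lt(max(abs(n0 - n1)), 1e-12)
  expect_error(rotate_grf_to_gravity(matrix(c(NA, 0, 0), 1), 6),
               "non-finite")
})

test_that("zero-phase low-pass has the closed-form Butterworth response", {
  fs <- 2400
  # unit DC gain
  expect_lt(max(abs(lowpass_filter(rep(2.5, 4800), fs) - 2.5)), 1e-9)

  # 100 Hz sinusoid attenuated to 1/(1 + (100/50)^6) = 1/65 (two passes)
  t <- seq(0, 2, by = 1 / fs)
  y <- lowpass_filter(sin(2 * pi * 100 * t), fs)
  core <- y[1200:3600]
  amp <- (max(core) - min(core)) / 2
  expect_lt(abs(amp - 1 / 65) / (1 / 65), 0.02)

  # zero phase: a symmetric bump keeps its peak index
  x <- exp(-((seq_along(t) - 2400) / 200)^2)
  expect_equal(which.max(lowpass_filter(x, fs)), which.max(x))

  # linearity
  set.seed(2)
  a <- rnorm(2000); b <- rnorm(2000)
  lhs <- lowpass_filter(3 * a - 2 * b, fs)
  rhs <- 3 * lowpass_filter(a, fs) - 2 * lowpass_filter(b, fs)
  expect_lt(max(abs(lhs - rhs)), 1e-10)
})

test_that("jump cross-correlation recovers the true integer lag", {
  for (L in c(-21L, 0L, 13L)) {
    cfg <- sim_config(n_subjects = 1, conditions = graded_conditions()[2, ],
                      steps_per_trial = 2, seed = 5, lag_samples = L,
                      noise_sd_pressure = 2)
    tr <- simulate_cohort(cfg)$trials[[1]]
    g <- rotate_grf_to_gravity(tr$grf, tr$condition$slope)
    est <- synchronize_streams(g[, 1], rowSums(tr$pressure), tr$fs_grf,
                               tr$fs_pressure)
    expect_identical(as.integer(est), L)
    expect_gt(attr(est, "peak_corr"), 0.7)
  }
  # ambiguous input (no jumps, pure noise) fails loudly
  set.seed(3)
  expect_error(
    synchronize_streams(rnorm(24000), rnorm(1000), 2400, 100),
    "ambiguous|floor")
})

test_that("stance detection matches the ledger and debounces dips", {
  tr <- tiny_trial()
  g <- rotate_grf_to_gravity(tr$grf, tr$condition$slope)
  vf <- lowpass_filter(g[, 1], tr$fs_grf)
  iv <- detect_steps(vf, tr$fs_grf, analysis_start_s = tr$analysis_start_s)
  expect_equal(nrow(iv), nrow(tr$true_step_intervals))
  expect_lte(max(abs(iv - tr$true_step_intervals)), 1)

  expect_identical(nrow(detect_steps(rep(0, 5000), 2400)), 0L)

  # a 20 ms sub-threshold dip inside a stance is bridged
  fs <- 1000
  x <- rep(0, 3000)
  x[1001:1400] <- 500
  x[1180:1199] <- 5       # 20 ms dip
  iv2 <- detect_steps(x, fs, threshold_N = 20, min_stance_s = 0.1,
                      min_flight_s = 0.05)
  expect_equal(nrow(iv2), 1)
  expect_equal(unname(iv2[1, ]), c(1001L, 1401L))
})

test_that("region summation partitions the 99 sensors", {
  expect_equal(unname(sum_regions(rep(1, 99))),
               as.vector(table(default_region_map())))
  expect_equal(unname(sum_regions(rep(0, 99))), rep(0, 5))
  set.seed(4)
  fr <- matrix(runif(99 * 7), 7)
  expect_lt(max(abs(rowSums(sum_regions(fr)) - rowSums(fr))), 1e-12)
  expect_error(sum_regions(rep(1, 98)), "99")
})

test_that("time normalization is exact on polynomials and tight on bumps", {
  expect_equal(time_normalize(rep(3, 50)), rep(3, 101))
  ramp <- seq(2, 7, length.out = 37)
  tn <- time_normalize(ramp)
  expect_equal(tn[1], 2)
  expect_equal(tn[101], 7)
  expect_lt(max(abs(tn - seq(2, 7, length.out = 101))), 1e-12)
  # 25-sample half-sine: linear interpolation error under 0.5% of peak
  hs <- sin(pi * seq(0, 1, length.out = 25))
  err <- abs(time_normalize(hs) - sin(pi * seq(0, 1, length.out = 101)))
  expect_lt(max(err), 0.005)
  expect_error(time_normalize(1), "at least 2")
})

test_that("extract_steps reproduces the ledger and is idempotent", {
  tr0 <- tiny_trial_clean()
  st0 <- extract_steps(tr0)
  expect_identical(attr(st0, "lag_used"), tr0$true_lag)
  tv <- t(sapply(tr0$true_steps_threshold, function(s) s$vert))
  ta <- t(sapply(tr0$true_steps_threshold, function(s) s$ap))
  # noise-free: the pipeline output equals the ledger reconstruction
  expect_lt(max(abs(st0$vert - tv)), 1e-12)
  expect_lt(max(abs(st0$ap - ta)), 1e-12)

  # with realistic noise: within 1% of the peak
  tr <- tiny_trial()
  st <- extract_steps(tr)
  tvn <- t(sapply(tr$true_steps_threshold, function(s) s$vert))
  expect_lt(max(abs(st$vert - tvn)) / max(tvn), 0.01)

  # contract: exactly 101 nodes everywhere; idempotence
  expect_equal(dim(st$pr), c(n_steps(st), 5, 101))
  st2 <- extract_steps(tr)
  expect_identical(st$pr, st2$pr)
  expect_identical(st$vert, st2$vert)
})

test_that("mass normalization scales pressures and forces consistently", {
  tr <- tiny_trial_clean()
  tr2 <- tr
  tr2$subject$mass <- 2 * tr$subject$mass
  s1 <- extract_steps(tr)
  s2 <- extract_steps(tr2)
  expect_equal(s2$pr, s1$pr / 2, tolerance = 1e-12)
  expect_equal(s2$vert, s1$vert / 2, tolerance = 1e-12)
})

test_that("left and right feet are handled identically", {
  cfg <- sim_config(n_subjects = 1, conditions = graded_conditions()[1, ],
                    steps_per_trial = 4, seed = 71)
  co <- simulate_cohort(cfg)
  ds <- preprocess_cohort(co)
  counts <- table(ds$meta$foot)
  expect_lte(abs(counts[["left"]] - counts[["right"]]), 1)
})
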