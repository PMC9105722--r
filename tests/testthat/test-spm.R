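test_that("summary metrics follow their definitions", {
  x <- sin(seq(0, pi, length.out = 101)) + 0.2
  expect_equal(rmse(x, x), 0)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(-x, x), -1)
  expect_equal(rmse(x + 0.1, x), 0.1)
  expect_equal(pearson_r(x + 0.1, x), 1)
  expect_error(pearson_r(rep(1, 101), x), "constant")
  expect_error(rmse(x, x[1:50]), "mismatch")
})

test_that("percent error normalizes by each step's range", {
  set.seed(6)
  truth <- t(replicate(4, sin(seq(0, pi, length.out = 101)) * runif(1, 1, 3)))
  rng <- apply(truth, 1, function(r) diff(range(r)))
  ec <- percent_error_curve(truth + 0.1 * rng, truth)
  expect_lt(max(abs(ec$mean_pct - 10)), 1e-12)
  expect_lt(max(ec$sd_pct), 1e-12)

  # offsets of +10% and -10% both count 10% in absolute error
  two <- truth[c(1, 1), ]
  pred <- two + c(0.1, -0.1) * diff(range(two[1, ]))
  ec2 <- percent_error_curve(pred, two)
  expect_lt(max(abs(ec2$mean_pct - 10)), 1e-12)
  expect_lt(max(ec2$sd_pct), 1e-12)

  # invariance under a common affine rescaling of pred and truth
  ecA <- percent_error_curve(truth + 0.07 * rng, truth)
  ecB <- percent_error_curve(3.5 * (truth + 0.07 * rng) + 2, 3.5 * truth + 2)
  expect_equal(ecA$mean_pct, ecB$mean_pct, tolerance = 1e-10)

  # zero-range steps are excluded, not divided by zero
  flat <- rbind(truth, 0)
  ec3 <- percent_error_curve(flat + 0.1, flat)
  expect_equal(ec3$n_steps, 4)
  expect_identical(attr(ec3, "excluded"), 1L)
})

test_that("the paired t field matches hand evaluation and is antisymmetric", {
  a <- matrix(0, 3, 101)
  b <- a
  a[, 1] <- c(1, 2, 3) # paired differences {1,2,3} at node 1
  b[, 1] <- 0
  set.seed(7)
  a[, -1] <- rnorm(300); b[, -1] <- rnorm(300)
  tf <- paired_t_field(a, b)
  expect_equal(tf$df, 2)
  expect_equal(tf$t[1], 2 * sqrt(3), tolerance = 1e-12)
  tf_swapped <- paired_t_field(b, a)
  expect_equal(tf$t, -tf_swapped$t, tolerance = 1e-12)
  expect_equal(dim(tf$residuals), c(3, 101))
  expect_lt(max(abs(colMeans(tf$residuals))), 1e-12)

  # a systematic shift drives the mean t in the opposite sign of b - a
  set.seed(8)
  base <- smooth_gaussian_field(10, 101, 8)
  shifted <- base + 0.5 + smooth_gaussian_field(10, 101, 8)
  expect_lt(mean(paired_t_field(base, shifted)$t), 0)

  expect_true(paired_t_field(a, a)$degenerate)
  expect_error(paired_t_field(a[1:2, ], b[1:2, ]), "3 pairs")
})

test_that("the smoothness estimator recovers the kernel FWHM", {
  set.seed(9)
  for (fw in c(5, 10, 20)) {
    est <- mean(replicate(10, estimate_fwhm(smooth_gaussian_field(50, 101, fw))))
    expect_lt(abs(est - fw) / fw, 0.15)
  }
  rough <- mean(replicate(10, estimate_fwhm(smooth_gaussian_field(50, 101, 0))))
  expect_lt(rough, 4)
  smooth5 <- estimate_fwhm(smooth_gaussian_field(50, 101, 5))
  expect_lt(rough, smooth5)
  expect_error(estimate_fwhm(matrix(0, 5, 101)), "all-zero")
})

test_that("RFT thresholds are monotone and bounded below by pointwise t", {
  t1 <- rft_threshold(0.05, 17, 101, 5)
  t2 <- rft_threshold(0.05, 17, 101, 10)
  t3 <- rft_threshold(0.05, 17, 101, 20)
  expect_gt(t1, t2)
  expect_gt(t2, t3)
  expect_gt(rft_threshold(0.01, 17, 101, 10), t2)
  # always above the pointwise two-tailed quantile
  for (fw in c(2, 10, 100)) {
    expect_gte(rft_threshold(0.05, 17, 101, fw), qt(0.975, 17))
  }
  # with a single resel the EC correction stays within 10% of the
  # pointwise quantile inflated by the 1D density term
  u100 <- rft_threshold(0.05, 17, 101, 100)
  expect_lt(u100 / qt(0.975, 17), 1.35)
})

test_that("threshold agrees with a sign-flip permutation oracle", {
  set.seed(4)
  ratios <- replicate(5, {
    d <- smooth_gaussian_field(18, 101, 10)
    rft_threshold(0.05, 17, 101, 10) /
      grfpress:::maxt_perm_threshold(d, 5000, 0.05)
  })
  expect_lt(abs(mean(ratios) - 1), 0.05)
})

test_that("spm_paired_test finds shifts where they are and controls FWE", {
  set.seed(11)
  J <- 18
  a <- smooth_gaussian_field(J, 101, 10)
  # huge global shift: one cluster spanning everything
  res <- spm_paired_test(a + 10, a + smooth_gaussian_field(J, 101, 10))
  expect_true(res$significant)
  expect_length(res$clusters, 1)
  expect_equal(unname(res$clusters[[1]]), c(1, 101))

  # shift confined to nodes 70-100 is localized to that region
  b <- smooth_gaussian_field(J, 101, 10)
  shift <- rep(0, 101); shift[70:100] <- 8
  res2 <- spm_paired_test(sweep(b, 2, -shift),
                          smooth_gaussian_field(J, 101, 10))
  expect_true(res2$significant)
  lo <- min(vapply(res2$clusters, `[[`, 1L, "from"))
  hi <- max(vapply(res2$clusters, `[[`, 1L, "to"))
  expect_gte(lo, 65)
  expect_lte(hi, 101)
  expect_equal(significant_nodes(res2),
               sum(vapply(res2$clusters, function(cl)
                 cl[["to"]] - cl[["from"]] + 1L, 1L)))

  # identical samples: degenerate field, reported as non-significant
  expect_warning(res3 <- spm_paired_test(a, a), "degenerate")
  expect_false(res3$significant)

  # type-I calibration at a reduced replicate count (the full 500-replicate
  # check runs with the acceptance suite)
  set.seed(12)
  rej <- mean(replicate(120, {
    spm_paired_test(smooth_gaussian_field(10, 101, 15),
                    smooth_gaussian_field(10, 101, 15))$significant
  }))
  expect_lt(rej, 0.15)
})

test_that("subject-level SPM samples a fixed number of steps with a seed", {
  set.seed(13)
  pred <- smooth_gaussian_field(40, 101, 10)
  obs <- pred + 0.1 * smooth_gaussian_field(40, 101, 10)
  r1 <- subject_level_spm(pred, obs, n_steps = 18, seed = 21)
  r2 <- subject_level_spm(pred, obs, n_steps = 18, seed = 21)
  expect_identical(attr(r1, "steps_used"), attr(r2, "steps_used"))
  expect_identical(r1$t, r2$t)
  expect_length(attr(r1, "steps_used"), 18)
  expect_equal(r1$df, 17)
  expect_warning(subject_level_spm(pred[1:10, ], obs[1:10, ], n_steps = 18),
                 "using all")
})
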