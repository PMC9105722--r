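test_that("least squares recovers the planted coefficients exactly", {
  ds <- tiny_steps()
  ab <- attr(ds, "true_coefficients")
  fit <- grf_lm(ds, "pooled")
  co <- coef(fit)
  expect_lt(max(abs(co[, "A"] - ab$A) / abs(ab$A)), 1e-8)
  expect_lt(max(abs(co[, "B"] - ab$B) / abs(ab$B)), 1e-8)

  fitc <- grf_lm(ds, "per_condition")
  expect_length(fitc$coefficients, 4)
  for (co in fitc$coefficients) {
    expect_lt(max(abs(co[, "A"] - ab$A) / abs(ab$A)), 1e-8)
  }
})

test_that("fit_linear equals a brute-force normal-equations solve", {
  cfg <- sim_config(n_subjects = 2, conditions = graded_conditions()[1:2, ],
                    steps_per_trial = 7, seed = 88)
  ds <- simulate_steps(cfg, noise_sd_pr = 0.02, noise_sd_grf = 0.01)
  ds50 <- ds[1:50]
  fit <- grf_lm(ds50, "pooled")
  # independent oracle: X'X beta = X'y assembled by hand
  X <- matrix(0, 50 * 101, 5)
  for (r in 1:5) X[, r] <- as.vector(t(ds50$pr[, r, ]))
  yv <- as.vector(t(ds50$vert))
  ya <- as.vector(t(ds50$ap))
  betaA <- solve(crossprod(X), crossprod(X, yv))
  betaB <- solve(crossprod(X), crossprod(X, ya))
  expect_lt(max(abs(coef(fit)[, "A"] - betaA)), 1e-10)
  expect_lt(max(abs(coef(fit)[, "B"] - betaB)), 1e-10)
})

test_that("coefficient bias vanishes as the step count grows", {
  ab <- planted_coefficients()
  err <- vapply(c(4, 16), function(k) {
    cfg <- sim_config(n_subjects = 2, conditions = graded_conditions()[1:2, ],
                      steps_per_trial = k, seed = 99)
    ds <- simulate_steps(cfg, noise_sd_grf = 0.05)
    max(abs(coef(grf_lm(ds, "pooled"))[, "A"] - ab$A))
  }, 1.0)
  expect_lt(err[2], err[1])
})

test_that("degenerate designs and unknown conditions fail loudly", {
  ds <- tiny_steps()[1:8]
  ds$pr[] <- 0
  expect_error(grf_lm(ds, "pooled"), "rank-deficient")

  full <- tiny_steps()
  fitc <- grf_lm(full[full$meta$slope == 0], "per_condition")
  uphill <- full[full$meta$slope == 6]
  expect_error(predict(fitc, uphill), "no coefficients")
})

test_that("predictions are linear and deterministic", {
  ds <- tiny_steps()
  fit <- grf_lm(ds, "pooled")
  p1 <- predict(fit, ds)
  expect_identical(p1, predict(fit, ds))

  doubled <- ds
  doubled$pr <- 2 * ds$pr
  p2 <- predict(fit, doubled)
  expect_equal(p2, 2 * p1, tolerance = 1e-12)

  zeroed <- ds[1:6]
  zeroed$pr[] <- 0
  expect_true(all(predict(fit, zeroed) == 0))

  # construction-exact predictions on linear-mode data
  expect_lt(max(abs(p1[, 1, ] - ds$vert)), 1e-8)
  expect_lt(max(abs(p1[, 2, ] - ds$ap)), 1e-8)
})

test_that("model JSON serialization round-trips", {
  ds <- tiny_steps()
  fit <- grf_lm(ds, "per_condition")
  path <- tempfile(fileext = ".json")
  write_grf_lm(fit, path)
  back <- read_grf_lm(path)
  expect_equal(coef(back), coef(fit), tolerance = 1e-12)
  p1 <- predict(fit, ds)
  p2 <- predict(back, ds)
  expect_equal(p1, p2, tolerance = 1e-12)
})
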