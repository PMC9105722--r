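test_that("stance waveforms respect boundary, footstrike and slope structure", {
  ph <- phase101
  ff <- list(footstrike = "forefoot")
  rf <- list(footstrike = "rearfoot")

  s26 <- synth_grf_step(list(speed = 2.6, slope = 0), ff, ph)
  s38 <- synth_grf_step(list(speed = 3.8, slope = 0), ff, ph)
  # zero at touchdown/toe-off, nonnegative, positive impulse
  for (s in list(s26, s38)) {
    expect_lt(abs(s$vert[1]), 1e-10)
    expect_lt(abs(s$vert[101]), 1e-10)
    expect_true(all(s$vert >= -1e-12))
    expect_gt(mean(s$vert), 0)
  }
  # active peak strictly increasing in speed
  expect_gt(max(s38$vert), max(s26$vert))
  speeds <- c(2.6, 3.0, 3.4, 3.8)
  peaks <- vapply(speeds, function(v)
    max(synth_grf_step(list(speed = v, slope = 0), rf, ph)$vert), 1.0)
  expect_true(all(diff(peaks) > 0))

  # forefoot: monotone rise over the first 40% (no impact transient);
  # rearfoot: a local impact maximum before 30% of stance
  expect_true(all(diff(s26$vert[1:41]) > -1e-12))
  srf <- synth_grf_step(list(speed = 3.0, slope = 0), rf, ph)
  expect_true(any(diff(srf$vert[1:31]) < 0))

  # A/P: braking first, propulsion second, one crossing region mid-stance
  ap <- s26$ap
  expect_lt(min(ap[1:48]), -0.1)
  expect_gt(max(ap[54:101]), 0.1)
  expect_true(all(ap[1:48] <= 1e-9))
  expect_true(all(ap[54:101] >= -1e-9))

  # uphill shifts impulse towards propulsion, downhill towards braking
  area <- function(s) c(br = sum(pmax(-s$ap, 0)), pr = sum(pmax(s$ap, 0)))
  up <- area(synth_grf_step(list(speed = 2.6, slope = 6), ff, ph))
  dn <- area(synth_grf_step(list(speed = 2.6, slope = -6), ff, ph))
  expect_gt(up[["pr"]] / up[["br"]], 1)
  expect_lt(dn[["pr"]] / dn[["br"]], 1)
})

test_that("pressure_from_force inverts the planted mapping exactly", {
  ph <- phase101
  sub <- list(mass = 70, footstrike = "rearfoot")
  s <- synth_grf_step(list(speed = 3.0, slope = 0), sub, ph)
  PR <- pressure_from_force(s, NULL, sub, "linear")
  expect_true(all(PR >= -1e-12))
  ab <- planted_coefficients()
  expect_lt(max(abs(PR %*% ab$A / sub$mass - s$vert)), 1e-10)
  expect_lt(max(abs(PR %*% ab$B / sub$mass - s$ap)), 1e-10)

  # exact least-squares recovery from the construction
  fitA <- lm.fit(PR / sub$mass, s$vert)$coefficients
  expect_lt(max(abs(fitA - ab$A) / abs(ab$A)), 1e-8)

  # zero force -> zero pressure (fallback path, no lobe attribute)
  z <- pressure_from_force(rep(0, 101), rep(0, 101), sub, "linear")
  expect_true(all(z == 0))

  # infeasible request fails loudly instead of clipping
  expect_error(
    pressure_from_force(rep(-1, 101), rep(0, 101), sub, "linear"),
    "infeasible")
})

test_that("saturating mode defeats linear models by a guaranteed margin", {
  cfg <- sim_config(n_subjects = 2,
                    conditions = graded_conditions()[c(1, 5, 8), ],
                    steps_per_trial = 10, seed = 42,
                    mapping_mode = "saturating")
  ds <- simulate_steps(cfg)
  fit <- grf_lm(ds, "pooled")
  res <- residuals(fit, ds)
  expect_gt(sqrt(mean(res$vert^2)), 0.02)
  expect_gt(sqrt(mean(res$ap^2)), 0.02)
})

test_that("cohort generation is deterministic and complete", {
  cfg <- sim_config(n_subjects = 2, conditions = graded_conditions()[1:2, ],
                    steps_per_trial = 3, seed = 9)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  # one trial per (subject, condition, foot)
  expect_length(c1$trials, 2 * 2 * 2)
  expect_identical(c1$trials[[3]]$pressure, c2$trials[[3]]$pressure)
  expect_identical(c1$trials[[3]]$grf, c2$trials[[3]]$grf)
  expect_identical(c1$ledger, c2$ledger)

  tr <- c1$trials[[1]]
  # ledger lists exactly steps_per_trial stance intervals
  expect_equal(nrow(tr$true_step_intervals), 3)
  # dual-rate lengths consistent within one frame
  expect_lt(abs(nrow(tr$pressure) * tr$fs_grf / tr$fs_pressure -
                  nrow(tr$grf)), tr$fs_grf / tr$fs_pressure + 1)
  # configured lag is recorded
  cfgl <- sim_config(n_subjects = 1, conditions = graded_conditions()[1, ],
                     steps_per_trial = 2, seed = 9, lag_samples = 37)
  expect_identical(simulate_cohort(cfgl)$trials[[1]]$true_lag, 37L)
})

test_that("flight phases carry no load and stance fraction is physiologic", {
  tr <- tiny_trial_clean()
  g <- rotate_grf_to_gravity(tr$grf, tr$condition$slope)
  iv <- tr$true_stance_times
  t <- (seq_len(nrow(g)) - 1) / tr$fs_grf
  run_start <- min(iv[, "on"])
  in_stance <- rep(FALSE, nrow(g))
  for (k in seq_len(nrow(iv)))
    in_stance[t >= iv[k, "on"] & t < iv[k, "off"]] <- TRUE
  flight <- t > run_start & t < max(iv[, "off"]) & !in_stance
  expect_lt(max(abs(g[flight, 1])), 1e-9)
  # stance fraction of the gait cycle between 25% and 50%
  cycle <- diff(iv[, "on"])
  frac <- (iv[-nrow(iv), "off"] - iv[-nrow(iv), "on"]) / cycle
  expect_true(all(frac > 0.25 & frac < 0.50))
})

test_that("simulated step datasets obey the conservation invariant", {
  ds <- tiny_steps()
  ab <- attr(ds, "true_coefficients")
  for (i in c(1, 17, n_steps(ds))) {
    recon <- drop(ab$A %*% ds$pr[i, , ])
    expect_lt(max(abs(recon - ds$vert[i, ])), 1e-10)
  }
  expect_equal(n_steps(ds), 3 * 4 * 2 * 5)
  expect_true(all(ds$pr >= 0))
})

test_that("an idiosyncratic gain scales forces but not pressures", {
  base <- sim_config(n_subjects = 1, conditions = graded_conditions()[1, ],
                     steps_per_trial = 4, seed = 55)
  gained <- base
  gained$idiosyncratic_gains <- c(S01 = 1.2)
  d0 <- simulate_steps(base)
  d1 <- simulate_steps(gained)
  expect_equal(d1$pr, d0$pr, tolerance = 1e-12)
  expect_equal(d1$vert, 1.2 * d0$vert, tolerance = 1e-12)
  expect_equal(d1$ap, 1.2 * d0$ap, tolerance = 1e-12)
})
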