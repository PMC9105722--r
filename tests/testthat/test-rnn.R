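test_that("analytic BPTT gradients match finite differences", {
  set.seed(1)
  spec <- rnn_spec(input_channels = 6, bilstm = c(4, 3), dropout = c(0, 0),
                   fc = c(5, 4))
  net <- rnn_init(spec, seed = 2)
  B <- 2L; Tn <- 7L
  X <- array(rnorm(6 * B * Tn), c(6, B, Tn))
  Y <- array(rnorm(2 * B * Tn), c(2, B, Tn))
  m0 <- array(0, c(1, 1, 1))
  res <- grfpress:::.rnn_loss_grad(net$params, X, Y, m0, m0, single = FALSE)
  eps <- 1e-5
  for (nm in names(net$params)) {
    p <- net$params[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      pp <- net$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- net$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      g_num <- (grfpress:::.rnn_loss_grad(pp, X, Y, m0, m0, FALSE)$loss -
                grfpress:::.rnn_loss_grad(pm, X, Y, m0, m0, FALSE)$loss) /
        (2 * eps)
      expect_lt(abs(g_num - res$grads[[nm]][i]),
                1e-4 * max(1, abs(g_num)))
    }
  }
  # gradients flow correctly through the inverted-dropout masks too
  set.seed(3)
  m1 <- array(sample(c(0, 2), 8 * B * Tn, TRUE), c(8, B, Tn))
  m2 <- array(sample(c(0, 1.25), 6 * B * Tn, TRUE), c(6, B, Tn))
  res2 <- grfpress:::.rnn_loss_grad(net$params, X, Y, m1, m2, FALSE)
  for (nm in c("Wf1", "Uf2", "Wfc1", "bb1")) {
    i <- 1L
    pp <- net$params; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- net$params; pm[[nm]][i] <- pm[[nm]][i] - eps
    g_num <- (grfpress:::.rnn_loss_grad(pp, X, Y, m1, m2, FALSE)$loss -
              grfpress:::.rnn_loss_grad(pm, X, Y, m1, m2, FALSE)$loss) /
      (2 * eps)
    expect_lt(abs(g_num - res2$grads[[nm]][i]), 1e-4 * max(1, abs(g_num)))
  }
})

test_that("network construction and inference are deterministic", {
  spec <- rnn_spec(reduced = TRUE)
  n1 <- rnn_init(spec, seed = 5)
  n2 <- rnn_init(spec, seed = 5)
  expect_identical(n1$params, n2$params)
  X <- array(rnorm(8 * 3 * 101), c(8, 3, 101))
  y1 <- grfpress:::.rnn_forward(n1$params, X)
  y2 <- grfpress:::.rnn_forward(n2$params, X)
  expect_identical(y1, y2)
  expect_true(all(is.finite(y1)))
  expect_equal(dim(y1), c(2, 3, 101))
  # 6-channel ablation variant builds and runs through the same code path
  n6 <- rnn_init(rnn_spec(input_channels = 6, reduced = TRUE), seed = 5)
  y6 <- grfpress:::.rnn_forward(n6$params, array(0, c(6, 2, 101)))
  expect_true(all(is.finite(y6)))
  expect_error(rnn_spec(input_channels = 7), "6 or 8")
})

test_that("Z-score statistics standardize training data without leakage", {
  ds <- tiny_steps()
  tr <- ds[ds$meta$subject_id != "S03"]
  te <- ds[ds$meta$subject_id == "S03"]
  st <- compute_norm_stats(tr)
  Xtr <- apply_norm(st, rnn_inputs(tr))
  for (ch in seq_len(dim(Xtr)[2])) {
    expect_lt(abs(mean(Xtr[, ch, ])), 1e-10)
    expect_lt(abs(sd(as.vector(Xtr[, ch, ])) - 1), 1e-10)
  }
  # training stats applied to another subject do not recentre it
  Xte <- apply_norm(st, rnn_inputs(te))
  expect_gt(max(abs(apply(Xte, 2, mean))), 1e-3)
  # mass varies across subjects, so its std is positive cohort-wide
  expect_gt(st$sd[["mass"]], 0)
  # a constant channel (slope within one condition) warns and gets unit sd
  one_cond <- ds[ds$meta$slope == 0 & ds$meta$speed == 2.6]
  expect_warning(compute_norm_stats(one_cond), "constant")
})

test_that("training reduces the loss and honours the epoch budget", {
  ds <- tiny_steps()
  spec <- rnn_spec(reduced = TRUE, dropout = c(0, 0))
  opt1 <- rnn_options(max_epochs = 1, val_fraction = 0)
  net1 <- grf_rnn(ds[seq(1, 120, by = 3)], spec = spec, options = opt1, seed = 3)
  expect_equal(nrow(net1$history), 1)

  # capacity check: a reduced network overfits 20 steps
  small <- tiny_steps()[seq(1, 120, by = 6)]
  net <- grf_rnn(small, spec = spec,
                 options = rnn_options(max_epochs = 300, val_fraction = 0,
                                       learning_rate = 2e-3,
                                       batch_size = 20),
                 seed = 4)
  expect_lt(tail(net$history$train_loss, 1),
            head(net$history$train_loss, 1))
  pred <- predict(net, small)
  train_rmse <- sqrt(mean((pred[, 1, ] - small$vert)^2 +
                            (pred[, 2, ] - small$ap)^2) / 2)
  expect_lt(train_rmse, 0.05)
})

test_that("prediction is deterministic and checks channel compatibility", {
  ds <- tiny_steps()[seq(1, 120, by = 4)]
  net <- grf_rnn(ds, spec = rnn_spec(reduced = TRUE),
                 options = rnn_options(max_epochs = 1, val_fraction = 0),
                 seed = 1)
  expect_identical(predict(net, ds), predict(net, ds))
  # a 6-channel network refuses 8-channel usage implicitly via its spec
  net6 <- grf_rnn(ds, spec = rnn_spec(input_channels = 6, reduced = TRUE),
                  options = rnn_options(max_epochs = 1, val_fraction = 0),
                  seed = 1)
  X8 <- rnn_inputs(ds, include_speed_slope = TRUE)
  expect_error(apply_norm(net6$norm_stats, X8))
})

test_that("fine-tuning splits are disjoint and arguments validated", {
  ds <- tiny_steps()
  tr <- ds[ds$meta$subject_id != "S02"]
  subj <- ds[ds$meta$subject_id == "S02"]
  net <- grf_rnn(tr, spec = rnn_spec(reduced = TRUE),
                 options = rnn_options(max_epochs = 2, val_fraction = 0),
                 seed = 2)
  tuned <- finetune_subject(net, subj, fraction = 0.10, seed = 9)
  ft <- attr(tuned, "finetune_idx")
  ho <- attr(tuned, "holdout_idx")
  expect_length(intersect(ft, ho), 0)
  expect_setequal(c(ft, ho), seq_len(n_steps(subj)))
  # stratified over conditions: every condition contributes
  keys <- condition_key(subj$meta$speed, subj$meta$slope)
  expect_setequal(unique(keys[ft]), unique(keys))
  expect_error(finetune_subject(net, subj, fraction = 0), "fraction")
  expect_error(finetune_subject(net, subj, fraction = 0.0001),
               "fewer than one")
})
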