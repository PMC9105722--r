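## Bidirectional LSTM sequence regression: spec, normalization, training
## (Adam, MSE over both GRF components and all 101 nodes), prediction and
## subject-specific fine-tuning.  The numerical kernels live in src/.

# ---- spec and options -------------------------------------------------------

#' Architecture specification for the GRF recurrent network
#'
#' The full-size network stacks a sequence input over 8 predictor channels
#' (five pressure regions, body mass, speed, slope), BiLSTM layers with 400
#' and 200 nodes with 30% and 20% dropout, fully connected layers with 300
#' and 150 nodes (hyperbolic tangent activations) and a final linear layer
#' with 2 outputs per node.  `reduced = TRUE` selects a desk-scale variant
#' (32/16 BiLSTM, 48/24 FC) with the same topology, suitable for CPU-bound
#' experiments and the test suite.
#'
#' @param input_channels 8, or 6 for the variant without the speed and slope
#'   predictors.
#' @param bilstm Hidden sizes of the two BiLSTM layers.
#' @param dropout Dropout probabilities after each BiLSTM layer (training
#'   only).
#' @param fc Sizes of the two hidden fully connected layers.
#' @param reduced Use the desk-scale layer sizes.
#' @return Object of class `rnn_spec`.
#' @export
rnn_spec <- function(input_channels = 8, bilstm = c(400, 200),
                     dropout = c(0.30, 0.20), fc = c(300, 150),
                     reduced = FALSE) {
  if (reduced) { bilstm <- c(32, 16); fc <- c(48, 24) }
  if (!input_channels %in% c(6, 8))
    stop("`input_channels` must be 6 or 8", call. = FALSE)
  if (any(bilstm < 1) || any(fc < 1))
    stop("layer sizes must be positive", call. = FALSE)
  if (any(dropout < 0) || any(dropout >= 1))
    stop("dropout must be in [0, 1)", call. = FALSE)
  structure(list(input_channels = as.integer(input_channels),
                 bilstm = as.integer(bilstm), dropout = dropout,
                 fc = as.integer(fc), output_nodes = 2L,
                 sequence_length = 101L),
            class = "rnn_spec")
}

#' Training options for the GRF recurrent network
#'
#' @param learning_rate Adam step size.
#' @param batch_size Sequences per minibatch.
#' @param max_epochs Maximum training epochs.
#' @param val_fraction Fraction of training steps held out for early
#'   stopping (0 disables early stopping).
#' @param patience Epochs without validation improvement before stopping.
#' @param shuffle_seed Seed for input-sequence shuffling, the validation
#'   split and the dropout draws.
#' @param finetune_lr_factor Learning-rate multiplier used by
#'   [finetune_subject()].
#' @param finetune_epochs Epochs used by [finetune_subject()].
#' @return Object of class `rnn_options`.
#' @export
rnn_options <- function(learning_rate = 1e-3, batch_size = 64,
                        max_epochs = 30, val_fraction = 0.1, patience = 5,
                        shuffle_seed = 1L, finetune_lr_factor = 0.1,
                        finetune_epochs = 20) {
  stopifnot_scalar_number(learning_rate, "learning_rate", positive = TRUE)
  if (max_epochs < 1) stop("`max_epochs` must be >= 1", call. = FALSE)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 val_fraction = val_fraction, patience = as.integer(patience),
                 shuffle_seed = as.integer(shuffle_seed),
                 finetune_lr_factor = finetune_lr_factor,
                 finetune_epochs = as.integer(finetune_epochs)),
            class = "rnn_options")
}

# ---- normalization ----------------------------------------------------------

#' Z-score normalization statistics from a training split
#'
#' Per-channel mean and standard deviation of the network's input channels,
#' computed over all steps and nodes of the *training* split only; test data
#' must be normalized with these statistics (no leakage).  A constant
#' channel is given unit standard deviation with a warning.
#'
#' @param data A [step_dataset()].
#' @param include_speed_slope Include the speed and slope channels
#'   (8-channel network) or not (6-channel ablation).
#' @return Object of class `norm_stats` with `mean`, `sd` and the channel
#'   names.
#' @export
compute_norm_stats <- function(data, include_speed_slope = TRUE) {
  X <- rnn_inputs(data, include_speed_slope)
  m <- apply(X, 2, mean)
  s <- apply(X, 2, function(v) sd(as.vector(v)))
  if (any(s == 0)) {
    warning("constant input channel(s) ",
            paste(dimnames(X)[[2]][s == 0], collapse = ", "),
            "; using unit standard deviation")
    s[s == 0] <- 1
  }
  structure(list(mean = m, sd = s, channels = dimnames(X)[[2]]),
            class = "norm_stats")
}

#' Apply Z-score normalization statistics
#'
#' @param stats A [compute_norm_stats()] result.
#' @param X Input array `n x channels x 101` (see [rnn_inputs()]).
#' @return Normalized array of the same shape.
#' @export
apply_norm <- function(stats, X) {
  stopifnot(inherits(stats, "norm_stats"), dim(X)[2] == length(stats$mean))
  for (ch in seq_along(stats$mean))
    X[, ch, ] <- (X[, ch, ] - stats$mean[ch]) / stats$sd[ch]
  X
}

#' Assemble the network input array from a step dataset
#'
#' Channels: the five mass-normalized region curves plus body mass and —
#' for the 8-channel network — treadmill speed and slope, the scalar
#' predictors replicated across the 101 nodes.
#'
#' @param data A [step_dataset()].
#' @param include_speed_slope Include speed and slope channels.
#' @return Array `n x C x 101` with channel dimnames.
#' @export
rnn_inputs <- function(data, include_speed_slope = TRUE) {
  n <- n_steps(data)
  C <- if (include_speed_slope) 8L else 6L
  X <- array(0, c(n, C, 101))
  X[, 1:5, ] <- data$pr
  X[, 6, ] <- data$meta$mass
  if (include_speed_slope) {
    X[, 7, ] <- data$meta$speed
    X[, 8, ] <- data$meta$slope
  }
  dimnames(X) <- list(NULL, c(paste0("PR", 1:5), "mass",
                              if (include_speed_slope) c("speed", "slope")),
                      NULL)
  X
}

# ---- parameter initialization -----------------------------------------------

init_mat <- function(nr, nc) {
  r <- 1 / sqrt(nc)
  matrix(runif(nr * nc, -r, r), nr, nc)
}

lstm_init <- function(H, C) {
  b <- numeric(4 * H)
  b[(H + 1):(2 * H)] <- 1        # forget-gate bias
  list(W = init_mat(4 * H, C), U = init_mat(4 * H, H), b = b)
}

#' Build an untrained GRF recurrent network
#'
#' Initializes all weights from the given seed (uniform, scaled by fan-in;
#' forget-gate biases start at 1).  The same seed always yields identical
#' initial weights.
#'
#' @param spec An [rnn_spec()].
#' @param seed Integer seed.
#' @return Object of class `grf_rnn` with `trained = FALSE`.
#' @export
rnn_init <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "rnn_spec"))
  p <- with_seed(seed, {
    C <- spec$input_channels
    H1 <- spec$bilstm[1]; H2 <- spec$bilstm[2]
    F1 <- spec$fc[1]; F2 <- spec$fc[2]
    l1f <- lstm_init(H1, C); l1b <- lstm_init(H1, C)
    l2f <- lstm_init(H2, 2 * H1); l2b <- lstm_init(H2, 2 * H1)
    list(Wf1 = l1f$W, Uf1 = l1f$U, bf1 = l1f$b,
         Wb1 = l1b$W, Ub1 = l1b$U, bb1 = l1b$b,
         Wf2 = l2f$W, Uf2 = l2f$U, bf2 = l2f$b,
         Wb2 = l2b$W, Ub2 = l2b$U, bb2 = l2b$b,
         Wfc1 = init_mat(F1, 2 * H2), bfc1 = numeric(F1),
         Wfc2 = init_mat(F2, F1), bfc2 = numeric(F2),
         Wfc3 = init_mat(2, F2), bfc3 = numeric(2))
  })
  structure(list(spec = spec, params = p, norm_stats = NULL,
                 history = NULL, trained = FALSE, seed = as.integer(seed)),
            class = "grf_rnn")
}

# ---- training ---------------------------------------------------------------

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# n x C x 101 array -> C x n x 101 cube expected by the kernels
to_cube <- function(X, idx = seq_len(dim(X)[1])) {
  aperm(X[idx, , , drop = FALSE], c(2, 1, 3))
}

targets_cube <- function(data, idx) {
  Y <- array(0, c(2, length(idx), 101))
  Y[1, , ] <- data$vert[idx, , drop = FALSE]
  Y[2, , ] <- data$ap[idx, , drop = FALSE]
  Y
}

dropout_mask <- function(p, channels, B, Tn) {
  if (p <= 0) return(array(0, c(1, 1, 1)))
  keep <- array(runif(channels * B * Tn) >= p, c(channels, B, Tn))
  keep / (1 - p)
}

mse_of <- function(params, X, Y) {
  pred <- .rnn_forward(params, X)
  mean((pred - Y)^2)
}

#' Train a GRF recurrent network (or continue training one)
#'
#' Minimizes the mean squared error over both output components and all 101
#' nodes with the Adam optimizer.  Input sequences are shuffled every epoch;
#' dropout is active during training only.  With `val_fraction > 0` a random
#' fraction of the training steps is held out and training stops early once
#' the validation loss has not improved for `patience` epochs (the best
#' weights are restored).  Fully deterministic given the seeds.
#'
#' @param network A `grf_rnn` from [rnn_init()] (or a trained one to
#'   continue from).
#' @param data Training [step_dataset()].
#' @param norm_stats Optional precomputed [compute_norm_stats()]; default:
#'   computed from `data`.
#' @param options An [rnn_options()].
#' @param learning_rate,max_epochs Optional overrides of `options`.
#' @return The trained `grf_rnn`; `$history` holds per-epoch training and
#'   validation loss.
#' @export
train_rnn <- function(network, data, norm_stats = NULL,
                      options = rnn_options(), learning_rate = NULL,
                      max_epochs = NULL) {
  stopifnot(inherits(network, "grf_rnn"), inherits(data, "step_dataset"))
  include_ss <- network$spec$input_channels == 8L
  norm_stats <- norm_stats %||% network$norm_stats %||%
    compute_norm_stats(data, include_ss)
  lr <- learning_rate %||% options$learning_rate
  n_epochs <- max_epochs %||% options$max_epochs
  X <- apply_norm(norm_stats, rnn_inputs(data, include_ss))
  n <- dim(X)[1]

  with_seed(options$shuffle_seed, {
    n_val <- if (options$val_fraction > 0)
      max(0L, min(n - 2L, round(options$val_fraction * n))) else 0L
    val_idx <- if (n_val > 0) sample.int(n, n_val) else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)
    Xval <- if (n_val > 0) to_cube(X, val_idx) else NULL
    Yval <- if (n_val > 0) targets_cube(data, val_idx) else NULL

    params <- network$params
    state <- adam_state(params)
    hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0))
    best <- list(loss = Inf, params = params, epoch = 0L)
    p1 <- network$spec$dropout[1]; p2 <- network$spec$dropout[2]
    H1 <- network$spec$bilstm[1]; H2 <- network$spec$bilstm[2]

    for (epoch in seq_len(n_epochs)) {
      ord <- sample(tr_idx)
      batches <- split(ord, ceiling(seq_along(ord) / options$batch_size))
      ep_loss <- 0
      for (b in batches) {
        Xb <- to_cube(X, b)
        Yb <- targets_cube(data, b)
        m1 <- dropout_mask(p1, 2 * H1, length(b), 101L)
        m2 <- dropout_mask(p2, 2 * H2, length(b), 101L)
        res <- .rnn_loss_grad(params, Xb, Yb, m1, m2)
        if (!is.finite(res$loss))
          stop(sprintf(
            "training diverged (non-finite loss at epoch %d); reduce the learning rate",
            epoch), call. = FALSE)
        upd <- adam_update(params, res$grads, state, lr)
        params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + res$loss * length(b)
      }
      ep_loss <- ep_loss / length(ord)
      vloss <- if (n_val > 0) mse_of(params, Xval, Yval) else NA_real_
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss,
                                     val_loss = vloss))
      monitor <- if (n_val > 0) vloss else ep_loss
      if (monitor < best$loss) {
        best <- list(loss = monitor, params = params, epoch = epoch)
      } else if (n_val > 0 && epoch - best$epoch >= options$patience) {
        break
      }
    }
    network$params <- if (n_val > 0) best$params else params
    network$norm_stats <- norm_stats
    network$history <- hist
    network$trained <- TRUE
    network$options <- options
    network
  })
}

#' Fit the GRF recurrent network to a step dataset
#'
#' Convenience wrapper: builds the network with [rnn_init()] and trains it
#' with [train_rnn()].
#'
#' @param data Training [step_dataset()].
#' @param spec An [rnn_spec()]; defaults to the reduced desk-scale
#'   architecture with 8 input channels.
#' @param options An [rnn_options()].
#' @param seed Seed for the weight initialization.
#' @return A trained `grf_rnn`.
#' @seealso [predict.grf_rnn()], [finetune_subject()], [grf_lm()]
#' @export
grf_rnn <- function(data, spec = rnn_spec(reduced = TRUE),
                    options = rnn_options(), seed = 1L) {
  net <- rnn_init(spec, seed)
  train_rnn(net, data, options = options)
}

#' Predict GRF curves with a trained recurrent network
#'
#' Deterministic inference (dropout inactive); inputs are normalized with
#' the network's stored training statistics.
#'
#' @param object A trained `grf_rnn`.
#' @param newdata A [step_dataset()].
#' @param ... Unused.
#' @return Array `n x 2 x 101` (vertical, anterior-posterior; body weights).
#' @export
predict.grf_rnn <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "step_dataset"))
  if (is.null(object$norm_stats))
    stop("network has no normalization statistics; train it first",
         call. = FALSE)
  include_ss <- object$spec$input_channels == 8L
  X <- rnn_inputs(newdata, include_ss)
  if (dim(X)[2] != object$spec$input_channels)
    stop(sprintf("network expects %d input channels, got %d",
                 object$spec$input_channels, dim(X)[2]), call. = FALSE)
  X <- apply_norm(object$norm_stats, X)
  Y <- .rnn_forward(object$params, to_cube(X))
  out <- array(0, c(dim(X)[1], 2, 101),
               dimnames = list(NULL, c("vert", "ap"), NULL))
  out[, 1, ] <- Y[1, , ]
  out[, 2, ] <- Y[2, , ]
  out
}

#' @export
residuals.grf_rnn <- function(object, data, ...) {
  pred <- predict(object, data)
  list(vert = data$vert - pred[, 1, ], ap = data$ap - pred[, 2, ])
}

#' @export
print.grf_rnn <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "BiLSTM GRF network: %d channels -> BiLSTM(%d, %d) -> FC(%d, %d) -> 2\n",
    s$input_channels, s$bilstm[1], s$bilstm[2], s$fc[1], s$fc[2]))
  if (x$trained) {
    h <- x$history
    cat(sprintf("  trained %d epochs; final train MSE %.4g%s\n", nrow(h),
                h$train_loss[nrow(h)],
                if (!is.na(h$val_loss[nrow(h)]))
                  sprintf(", val MSE %.4g", h$val_loss[nrow(h)]) else ""))
  } else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.grf_rnn <- function(object, data = NULL, ...) {
  print(object)
  if (!is.null(data)) {
    m <- step_metrics(predict(object, data), data)
    agg <- stats::aggregate(cbind(rmse, r) ~ component, data = m, mean)
    cat("\nMean per-step metrics:\n")
    print(agg, digits = 3)
  }
  invisible(object)
}

#' @export
plot.grf_rnn <- function(x, ...) {
  if (is.null(x$history)) stop("no training history to plot", call. = FALSE)
  h <- x$history
  plot(h$epoch, h$train_loss, type = "b", pch = 16, xlab = "epoch",
       ylab = "MSE loss", ...)
  if (any(!is.na(h$val_loss))) {
    lines(h$epoch, h$val_loss, type = "b", pch = 1, lty = 2)
    legend("topright", c("training", "validation"), pch = c(16, 1),
           lty = c(1, 2), bty = "n")
  }
  invisible(x)
}

# ---- subject-specific fine-tuning -------------------------------------------

#' Fine-tune a generic network on a fraction of one subject's steps
#'
#' Continues training a generic (leave-subject-out) network on a small
#' random fraction of the target subject's steps — emulating a brief
#' calibration session — sampled stratified by condition with a stated
#' seed.  Evaluation must use only the remaining held-out steps; their
#' indices are attached to the result.
#'
#' @param generic_network A trained `grf_rnn` whose training data excluded
#'   the target subject.
#' @param subject_data [step_dataset()] with all steps of the target
#'   subject.
#' @param fraction Fraction of steps used for fine-tuning (default 0.10).
#' @param options [rnn_options()]; `finetune_lr_factor` and
#'   `finetune_epochs` control the continued training.
#' @param seed Seed for the step sampling.
#' @return A fine-tuned `grf_rnn` with attributes `"finetune_idx"` and
#'   `"holdout_idx"` (disjoint by construction).
#' @export
finetune_subject <- function(generic_network, subject_data, fraction = 0.10,
                             options = generic_network$options %||%
                               rnn_options(), seed = 1L) {
  stopifnot(inherits(generic_network, "grf_rnn"),
            isTRUE(generic_network$trained))
  if (fraction <= 0 || fraction >= 1)
    stop("`fraction` must be in (0, 1)", call. = FALSE)
  n <- n_steps(subject_data)
  if (round(fraction * n) < 1)
    stop("`fraction` yields fewer than one fine-tuning step", call. = FALSE)
  keys <- condition_key(subject_data$meta$speed, subject_data$meta$slope)
  idx <- with_seed(seed, {
    unlist(lapply(split(seq_len(n), keys), function(g)
      sample(g, max(1L, round(fraction * length(g))))), use.names = FALSE)
  })
  holdout <- setdiff(seq_len(n), idx)
  ft_opts <- options
  ft_opts$val_fraction <- 0            # tiny sets: train on all samples
  ft_opts$shuffle_seed <- child_seed(seed, 17L)
  tuned <- train_rnn(generic_network, subject_data[idx],
                     norm_stats = generic_network$norm_stats,
                     options = ft_opts,
                     learning_rate = options$learning_rate *
                       options$finetune_lr_factor,
                     max_epochs = options$finetune_epochs)
  attr(tuned, "finetune_idx") <- sort(idx)
  attr(tuned, "holdout_idx") <- holdout
  tuned
}
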