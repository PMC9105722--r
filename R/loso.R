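## Leave-one-subject-out validation, the speed/slope ablation, the
## subject-specific fine-tuning experiment, and report generation.

#' Leave-one-subject-out folds
#'
#' @param data A [step_dataset()].
#' @return List of folds, each `list(train_subjects, test_subject)`; every
#'   subject appears as test exactly once.
#' @export
loso_split <- function(data) {
  subjects <- sort(unique(data$meta$subject_id))
  if (length(subjects) < 2)
    stop("leave-one-subject-out needs at least 2 subjects", call. = FALSE)
  lapply(subjects, function(s)
    list(train_subjects = setdiff(subjects, s), test_subject = s))
}

#' Run a leave-one-subject-out validation of a GRF estimator
#'
#' For each fold the chosen model is trained on the training subjects only —
#' including, for the recurrent network, its Z-score normalization
#' statistics — and predicts every step of the held-out subject.  Per-fold
#' network seeds are derived from `seed` and the fold index, so the whole
#' run is reproducible.
#'
#' @param data A [step_dataset()].
#' @param model `"linear_per_condition"`, `"linear_pooled"`, `"rnn_full"`
#'   (8 input channels) or `"rnn_no_speed_slope"` (6 channels).
#' @param spec,options Network settings for the `rnn_*` models.
#' @param seed Base seed for per-fold network initialization.
#' @return An object of class `grf_loso`: `predictions` (`n x 2 x 101`,
#'   aligned with `data`), `metrics` (per-step data frame), `folds`,
#'   per-fold `models` descriptors and (for networks) `norm_stats`.
#' @export
run_loso <- function(data,
                     model = c("linear_per_condition", "linear_pooled",
                               "rnn_full", "rnn_no_speed_slope"),
                     spec = rnn_spec(reduced = TRUE), options = rnn_options(),
                     seed = 1L) {
  model <- match.arg(model)
  folds <- loso_split(data)
  n <- n_steps(data)
  pred <- array(NA_real_, c(n, 2, 101),
                dimnames = list(NULL, c("vert", "ap"), NULL))
  models <- list()
  skipped <- 0L
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    tr <- which(data$meta$subject_id %in% fold$train_subjects)
    te <- which(data$meta$subject_id == fold$test_subject)
    train <- data[tr]
    test <- data[te]
    if (startsWith(model, "linear")) {
      scope <- if (model == "linear_pooled") "pooled" else "per_condition"
      fit <- grf_lm(train, scope = scope)
      if (scope == "per_condition") {
        known <- names(fit$coefficients)
        ok <- condition_key(test$meta$speed, test$meta$slope) %in% known
        if (!all(ok)) {
          skipped <- skipped + sum(!ok)
          te <- te[ok]
          test <- data[te]
        }
      }
      if (length(te)) pred[te, , ] <- predict(fit, test)
      models[[fold$test_subject]] <- fit
    } else {
      sp <- spec
      sp$input_channels <- if (model == "rnn_full") 8L else 6L
      net <- rnn_init(sp, seed = child_seed(seed, f))
      opts <- options
      opts$shuffle_seed <- child_seed(seed, 1000L + f)
      net <- train_rnn(net, train, options = opts)
      pred[te, , ] <- predict(net, test)
      models[[fold$test_subject]] <- net
    }
  }
  metrics <- step_metrics(pred, data)
  structure(list(predictions = pred, metrics = metrics, folds = folds,
                 model = model, models = models, seed = seed,
                 skipped_steps = skipped, data_meta = data$meta),
            class = "grf_loso")
}

#' @export
print.grf_loso <- function(x, ...) {
  cat(sprintf("LOSO validation of %s: %d folds, %d steps\n",
              x$model, length(x$folds), nrow(x$data_meta)))
  agg <- subject_mean_metrics(x)
  res <- stats::aggregate(cbind(rmse, r) ~ component, data = agg, mean)
  cat(sprintf("  mean test RMSE (BW): vert %.4f, ap %.4f; mean r: vert %.3f, ap %.3f\n",
              res$rmse[res$component == "vert"],
              res$rmse[res$component == "ap"],
              res$r[res$component == "vert"],
              res$r[res$component == "ap"]))
  invisible(x)
}

# prediction array slice as an n x 101 matrix (robust to single steps)
pred_mat <- function(P, i, comp) {
  if (is.logical(i)) i <- which(i)
  matrix(P[i, comp, ], nrow = length(i))
}

# per-step -> per-subject means (per component): every test subject carries
# equal weight in cohort summaries regardless of step count
subject_mean_metrics <- function(loso) {
  m <- loso$metrics
  m <- m[is.finite(m$rmse), ]
  stats::aggregate(cbind(rmse, r) ~ subject_id + component, data = m, mean)
}

#' Cohort-level mean test metrics of a LOSO run
#'
#' Averages per-step RMSE and Pearson r within each test subject first and
#' then across subjects (mean and SD), per component.
#'
#' @param loso A [run_loso()] result.
#' @return Data frame with columns `component`, `rmse`, `rmse_sd`, `r`,
#'   `r_sd`, `n_subjects`.
#' @export
loso_summary <- function(loso) {
  agg <- subject_mean_metrics(loso)
  out <- do.call(rbind, lapply(split(agg, agg$component), function(g)
    data.frame(component = g$component[1], rmse = mean(g$rmse),
               rmse_sd = sd(g$rmse), r = mean(g$r), r_sd = sd(g$r),
               n_subjects = nrow(g))))
  rownames(out) <- NULL
  out
}

#' Cohort report: metrics, percent error and SPM per condition
#'
#' Per condition and GRF component, reports the across-subject mean and SD
#' of RMSE and Pearson r, the mean percent-error curve, a cohort-level SPM
#' paired t-test comparing subject-mean predicted against subject-mean
#' measured curves (paired over subjects), and stance-window mean errors
#' for early stance (0-20%) and late stance (75-100%).
#'
#' @param loso A [run_loso()] result.
#' @param data The [step_dataset()] the run was computed on.
#' @param alpha SPM significance level.
#' @return Object of class `grf_report` with `table` (one row per condition
#'   and component), `spm` and `error_curves` (nested lists).
#' @export
cohort_report <- function(loso, data, alpha = 0.05) {
  stopifnot(inherits(loso, "grf_loso"))
  meta <- data$meta
  conds <- unique(meta[, c("speed", "slope")])
  rows <- list(); spms <- list(); curves <- list()
  persubj <- subject_mean_metrics(loso)
  for (ci in seq_len(nrow(conds))) {
    ck <- condition_key(conds$speed[ci], conds$slope[ci])
    in_cond <- meta$speed == conds$speed[ci] & meta$slope == conds$slope[ci]
    for (comp in c("vert", "ap")) {
      truth <- if (comp == "vert") data$vert else data$ap
      ok <- in_cond & is.finite(loso$predictions[, comp, 1])
      m <- loso$metrics
      m <- m[m$component == comp & is.finite(m$rmse) &
               m$speed == conds$speed[ci] & m$slope == conds$slope[ci], ]
      ms <- stats::aggregate(cbind(rmse, r) ~ subject_id, data = m, mean)
      # subject-mean curves, paired over subjects
      sids <- sort(unique(meta$subject_id[ok]))
      pm <- t(vapply(sids, function(s) {
        i <- which(ok & meta$subject_id == s)
        colMeans(pred_mat(loso$predictions, i, comp))
      }, numeric(101)))
      tm <- t(vapply(sids, function(s) {
        i <- which(ok & meta$subject_id == s)
        colMeans(truth[i, , drop = FALSE])
      }, numeric(101)))
      spm <- if (length(sids) >= 3) spm_paired_test(pm, tm, alpha) else NULL
      ec <- percent_error_curve(
        pred_mat(loso$predictions, ok, comp), truth[ok, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        speed = conds$speed[ci], slope = conds$slope[ci], component = comp,
        model = loso$model,
        rmse = mean(ms$rmse), rmse_sd = sd(ms$rmse),
        r = mean(ms$r), r_sd = sd(ms$r), n_subjects = nrow(ms),
        err_0_20 = mean(ec$mean_pct[1:21]),
        err_75_100 = mean(ec$mean_pct[76:101]),
        sig_nodes = if (is.null(spm)) NA_integer_ else significant_nodes(spm))
      spms[[ck]][[comp]] <- spm
      curves[[ck]][[comp]] <- ec
    }
  }
  structure(list(table = do.call(rbind, rows), spm = spms,
                 error_curves = curves, model = loso$model, alpha = alpha),
            class = "grf_report")
}

#' @export
print.grf_report <- function(x, ...) {
  cat(sprintf("Cohort report for %s (alpha = %g)\n", x$model, x$alpha))
  print(x$table, digits = 3)
  invisible(x)
}

#' Subject-level report with exemplar ranking
#'
#' Runs a subject-level SPM (on `n_spm_steps` sampled steps) per subject,
#' condition and component, ranks subjects by their average percent error
#' (mean of the percent-error curve over all nodes and conditions), and
#' tags the lowest, median and highest-error subjects per component.
#'
#' @param loso A [run_loso()] result.
#' @param data The matching [step_dataset()].
#' @param n_spm_steps Steps sampled per subject-level SPM (default 18).
#' @param seed Sampling seed.
#' @param alpha Significance level.
#' @return Object of class `grf_subject_report`: `ranking` data frame (with
#'   `exemplar` tags `"low"`/`"median"`/`"high"`) and `spm` nested list.
#' @export
subject_report <- function(loso, data, n_spm_steps = 18, seed = 1L,
                           alpha = 0.05) {
  meta <- data$meta
  subjects <- sort(unique(meta$subject_id))
  conds <- unique(meta[, c("speed", "slope")])
  spms <- list(); rows <- list()
  for (s in subjects) {
    for (comp in c("vert", "ap")) {
      truth <- if (comp == "vert") data$vert else data$ap
      errs <- c()
      for (ci in seq_len(nrow(conds))) {
        i <- which(meta$subject_id == s & meta$speed == conds$speed[ci] &
                     meta$slope == conds$slope[ci] &
                     is.finite(loso$predictions[, comp, 1]))
        if (length(i) < 3) next
        ck <- condition_key(conds$speed[ci], conds$slope[ci])
        spm <- subject_level_spm(
          pred_mat(loso$predictions, i, comp),
          truth[i, , drop = FALSE], n_steps = n_spm_steps,
          seed = child_seed(seed, ci * 131L + match(comp, c("vert", "ap"))),
          alpha = alpha)
        spms[[s]][[ck]][[comp]] <- spm
        ec <- percent_error_curve(pred_mat(loso$predictions, i, comp),
                                  truth[i, , drop = FALSE])
        errs <- c(errs, mean(ec$mean_pct))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s, component = comp, mean_pct_error = mean(errs))
    }
  }
  ranking <- do.call(rbind, rows)
  ranking$exemplar <- NA_character_
  for (comp in c("vert", "ap")) {
    i <- which(ranking$component == comp)
    o <- i[order(ranking$mean_pct_error[i])]
    ranking$exemplar[o[1]] <- "low"
    ranking$exemplar[o[ceiling(length(o) / 2)]] <- "median"
    ranking$exemplar[o[length(o)]] <- "high"
  }
  structure(list(ranking = ranking, spm = spms, seed = seed),
            class = "grf_subject_report")
}

#' @export
print.grf_subject_report <- function(x, ...) {
  cat("Subject-level report (average percent error by component):\n")
  print(x$ranking, digits = 3)
  invisible(x)
}

#' Generic versus subject-specific fine-tuning experiment
#'
#' Trains a generic network on all subjects except the target, fine-tunes a
#' copy on a small fraction of the target's steps (stratified by
#' condition), and evaluates both on the identical held-out remainder:
#' held-out RMSE per component, mean percent error, and the total number of
#' significant SPM nodes summed over conditions.
#'
#' @param data A [step_dataset()] containing the target subject.
#' @param target_subject Subject id to personalize for.
#' @param fraction Fraction of the target's steps used for fine-tuning.
#' @param spec,options Network settings.
#' @param seed Base seed (network init, step sampling, SPM sampling).
#' @param alpha SPM significance level.
#' @return Object of class `grf_finetune`: `comparison` data frame (one row
#'   per component and model with `rmse`, `mean_pct_error`, `sig_nodes`),
#'   the two networks, and the held-out step indices.
#' @export
finetune_experiment <- function(data, target_subject, fraction = 0.10,
                                spec = rnn_spec(reduced = TRUE),
                                options = rnn_options(), seed = 1L,
                                alpha = 0.05) {
  stopifnot(target_subject %in% data$meta$subject_id)
  tr <- which(data$meta$subject_id != target_subject)
  te <- which(data$meta$subject_id == target_subject)
  generic <- grf_rnn(data[tr], spec = spec, options = options,
                     seed = child_seed(seed, 1L))
  subject_data <- data[te]
  tuned <- finetune_subject(generic, subject_data, fraction = fraction,
                            options = options, seed = child_seed(seed, 2L))
  holdout <- attr(tuned, "holdout_idx")
  stopifnot(length(intersect(attr(tuned, "finetune_idx"), holdout)) == 0)
  eval_data <- subject_data[holdout]
  rows <- list()
  for (m in c("generic", "subject_specific")) {
    net <- if (m == "generic") generic else tuned
    pred <- predict(net, eval_data)
    for (comp in c("vert", "ap")) {
      truth <- if (comp == "vert") eval_data$vert else eval_data$ap
      ec <- percent_error_curve(pred_mat(pred, seq_len(nrow(truth)), comp),
                                truth)
      # significant nodes summed over conditions (subject-level SPM)
      keys <- condition_key(eval_data$meta$speed, eval_data$meta$slope)
      sig <- 0L
      for (ck in unique(keys)) {
        i <- which(keys == ck)
        if (length(i) < 3) next
        spm <- subject_level_spm(pred_mat(pred, i, comp),
                                 truth[i, , drop = FALSE],
                                 seed = child_seed(seed, 3L), alpha = alpha)
        sig <- sig + significant_nodes(spm)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        model = m, component = comp,
        rmse = sqrt(mean((pred[, comp, ] - truth)^2)),
        mean_pct_error = mean(ec$mean_pct), sig_nodes = sig)
    }
  }
  structure(list(comparison = do.call(rbind, rows), generic = generic,
                 tuned = tuned, holdout_idx = holdout,
                 target_subject = target_subject),
            class = "grf_finetune")
}

#' @export
print.grf_finetune <- function(x, ...) {
  cat(sprintf("Fine-tuning experiment for subject %s (held-out steps: %d)\n",
              x$target_subject, length(x$holdout_idx)))
  print(x$comparison, digits = 3)
  invisible(x)
}

#' @export
plot.grf_loso <- function(x, data, condition = NULL, component = "vert",
                          ...) {
  meta <- x$data_meta
  if (is.null(condition)) condition <- c(meta$speed[1], meta$slope[1])
  ok <- meta$speed == condition[1] & meta$slope == condition[2] &
    is.finite(x$predictions[, component, 1])
  truth <- if (component == "vert") data$vert else data$ap
  mp <- colMeans(x$predictions[ok, component, , drop = TRUE])
  mt <- colMeans(truth[ok, , drop = FALSE])
  matplot(0:100, cbind(mt, mp), type = "l", lty = c(1, 2), lwd = 2,
          col = c("black", "red3"), xlab = "% stance",
          ylab = sprintf("%s GRF (BW)", component), ...)
  legend("topright", c("measured", x$model), lty = c(1, 2), lwd = 2,
         col = c("black", "red3"), bty = "n")
  invisible(x)
}
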