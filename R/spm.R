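## Evaluation stack: RMSE, Pearson r, range-normalized time-continuous
## percent error, and two-tailed paired SPM t-tests on 101-node curves with
## random-field-theory (RFT) critical thresholds and suprathreshold clusters.

# ---- summary metrics --------------------------------------------------------

#' Root mean squared error between two curves
#' @param pred,obs Numeric vectors of equal length (body weights).
#' @return RMSE in the units of the inputs.
#' @export
rmse <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("length mismatch", call. = FALSE)
  sqrt(mean((pred - obs)^2))
}

#' Pearson correlation between two curves
#' @param pred,obs Numeric vectors of equal length; both must be
#'   non-constant.
#' @return Pearson's r.
#' @export
pearson_r <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("length mismatch", call. = FALSE)
  if (sd(pred) == 0 || sd(obs) == 0)
    stop("correlation undefined for constant input", call. = FALSE)
  cor(pred, obs)
}

#' Per-step RMSE and correlation for a prediction array
#'
#' @param pred Array `n x 2 x 101` as returned by the `predict` methods.
#' @param data The matching [step_dataset()].
#' @return Data frame with one row per step and component: subject,
#'   condition, foot, `component` (`"vert"`/`"ap"`), `rmse` (BW) and `r`.
#' @export
step_metrics <- function(pred, data) {
  n <- n_steps(data)
  stopifnot(dim(pred)[1] == n)
  one <- function(comp, truth) {
    data.frame(data$meta[, c("subject_id", "speed", "slope", "foot")],
               component = comp,
               rmse = sqrt(rowMeans((pred[, comp, ] - truth)^2)),
               r = vapply(seq_len(n), function(i) {
                 p <- pred[i, comp, ]
                 if (anyNA(p) || sd(truth[i, ]) == 0 || sd(p) == 0)
                   NA_real_
                 else cor(p, truth[i, ])
               }, 1.0),
               stringsAsFactors = FALSE)
  }
  rbind(one("vert", data$vert), one("ap", data$ap))
}

#' Range-normalized time-continuous percent error
#'
#' For each step the absolute prediction error at every stance node is
#' divided by that step's GRF range (max - min of the measured curve) and
#' expressed in percent; the mean and standard deviation across steps are
#' returned per node.  Steps with zero range are excluded (their count is
#' recorded in attribute `"excluded"`).
#'
#' @param pred,obs Numeric matrices `n x 101` (predicted and measured curves
#'   of one component).
#' @return An object of class `error_curve`: list with `mean_pct`, `sd_pct`
#'   (vectors of length 101) and `n_steps`.
#' @export
percent_error_curve <- function(pred, obs) {
  stopifnot(all(dim(pred) == dim(obs)))
  rng <- apply(obs, 1, function(x) diff(range(x)))
  keep <- rng > 0
  e <- 100 * abs(pred[keep, , drop = FALSE] - obs[keep, , drop = FALSE]) /
    rng[keep]
  structure(list(mean_pct = colMeans(e),
                 sd_pct = apply(e, 2, sd),
                 n_steps = sum(keep)),
            class = "error_curve", excluded = sum(!keep))
}

#' @export
print.error_curve <- function(x, ...) {
  cat(sprintf(
    "Percent-error curve over %d steps: mean %.2f%% (node range %.2f-%.2f%%)\n",
    x$n_steps, mean(x$mean_pct), min(x$mean_pct), max(x$mean_pct)))
  invisible(x)
}

#' @export
plot.error_curve <- function(x, ylim = NULL, xlab = "% stance",
                             ylab = "absolute error (% of step range)", ...) {
  q <- 0:100
  up <- x$mean_pct + x$sd_pct; lo <- pmax(0, x$mean_pct - x$sd_pct)
  if (is.null(ylim)) ylim <- c(0, max(up))
  plot(q, x$mean_pct, type = "n", ylim = ylim, xlab = xlab, ylab = ylab, ...)
  polygon(c(q, rev(q)), c(up, rev(lo)), col = adjustcolor("grey60", 0.5),
          border = NA)
  lines(q, x$mean_pct, lwd = 2)
  invisible(x)
}

# ---- SPM --------------------------------------------------------------------

#' Node-wise paired t statistic field
#'
#' Computes `t(q) = mean(d(q)) / (sd(d(q)) / sqrt(J))` for the paired
#' differences `d = a - b` at each of the 101 nodes, with `J - 1` degrees of
#' freedom, and returns the mean-centred differences for smoothness
#' estimation.
#'
#' @param sample_a,sample_b Numeric matrices `J x Q` of matched curves.
#' @return List with `t` (length-Q field), `df`, and `residuals` (`J x Q`).
#'   If the difference field has zero variance everywhere the result carries
#'   `degenerate = TRUE`.
#' @export
paired_t_field <- function(sample_a, sample_b) {
  stopifnot(all(dim(sample_a) == dim(sample_b)))
  J <- nrow(sample_a)
  if (J < 3) stop("need at least 3 pairs", call. = FALSE)
  d <- sample_a - sample_b
  m <- colMeans(d)
  s <- apply(d, 2, sd)
  degenerate <- all(s < .Machine$double.eps^0.5)
  t <- ifelse(s > 0, m / (s / sqrt(J)), 0)
  list(t = t, df = J - 1, residuals = sweep(d, 2, m), degenerate = degenerate)
}

#' Estimate the smoothness (FWHM) of a 1D residual field
#'
#' Standard random-field-theory gradient estimator: residual curves are
#' normalized to unit sum of squares per node, the mean squared gradient of
#' the normalized residuals along the node axis is computed, and
#' `FWHM = sqrt(4 * log(2) / mean squared gradient)`, clamped to
#' \[1, n_nodes\] node units.
#'
#' @param residuals Numeric matrix `J x Q` (e.g. from [paired_t_field()]).
#' @return FWHM in node units.
#' @export
estimate_fwhm <- function(residuals) {
  J <- nrow(residuals); Q <- ncol(residuals)
  if (J < 3) stop("need at least 3 residual curves", call. = FALSE)
  ssq <- colSums(residuals^2)
  if (all(ssq < .Machine$double.eps))
    stop("all-zero residual field", call. = FALSE)
  u <- sweep(residuals, 2, sqrt(pmax(ssq, .Machine$double.eps)), `/`)
  g <- u[, -1, drop = FALSE] - u[, -Q, drop = FALSE]   # unit node spacing
  v <- mean(colSums(g^2))
  fwhm <- sqrt(4 * log(2) / max(v, .Machine$double.eps))
  min(max(fwhm, 1), Q)
}

#' Random-field-theory critical threshold for a 1D t field
#'
#' Smallest threshold `u` at which the expected Euler characteristic of the
#' suprathreshold excursion set of a smooth 1D t random field equals the
#' per-tail significance level: `P(T > u) + resels * rho1(u) = alpha_tail`,
#' with `resels = (n_nodes - 1) / fwhm` and the standard 1D
#' Euler-characteristic density for t fields
#' `rho1(u) = sqrt(4 log 2) / (2 pi) * (1 + u^2 / df)^(-(df - 1) / 2)`.
#' Solved numerically to 1e-6.
#'
#' @param alpha Family-wise significance level.
#' @param df Degrees of freedom.
#' @param n_nodes Field length in nodes.
#' @param fwhm Field smoothness in nodes (>= 1).
#' @param two_tailed If `TRUE` (default), `alpha/2` is allotted per tail.
#' @return Critical threshold `t*` (> 0).
#' @export
rft_threshold <- function(alpha = 0.05, df, n_nodes = 101, fwhm,
                          two_tailed = TRUE) {
  stopifnot(alpha > 0, alpha < 1, df >= 1, fwhm >= 1)
  a_tail <- if (two_tailed) alpha / 2 else alpha
  resels <- (n_nodes - 1) / fwhm
  ec <- function(u) {
    rho0 <- pt(u, df, lower.tail = FALSE)
    rho1 <- sqrt(4 * log(2)) / (2 * pi) * (1 + u^2 / df)^(-(df - 1) / 2)
    rho0 + resels * rho1 - a_tail
  }
  lo <- qt(1 - a_tail, df)   # pointwise quantile is always a lower bound
  hi <- lo + 1
  while (ec(hi) > 0 && hi < 1e3) hi <- hi * 2
  if (ec(hi) > 0) stop("no RFT threshold found in search bracket",
                       call. = FALSE)
  uniroot(ec, c(lo, hi), tol = 1e-6)$root
}

#' Two-tailed paired SPM t test on 101-node curves
#'
#' Composes [paired_t_field()], [estimate_fwhm()] and [rft_threshold()]:
#' computes the paired t field of `sample_a - sample_b`, estimates the
#' field's smoothness from the residuals, derives the RFT critical
#' threshold at level `alpha` (two-tailed), and reports maximal runs of
#' nodes with `|t|` above the threshold as significant clusters.
#'
#' A degenerate difference field (zero variance everywhere, e.g. perfect
#' predictions) is reported as "no significant clusters" with a warning
#' rather than an error.
#'
#' @param sample_a,sample_b Matched `J x Q` curve samples.
#' @param alpha Family-wise significance level.
#' @return An object of class `spm_result` with fields `t` (the statistic
#'   field), `df`, `fwhm`, `alpha`, `t_critical`, `clusters` (list of
#'   `c(from, to)` node intervals, 1-based inclusive) and `significant`.
#' @export
spm_paired_test <- function(sample_a, sample_b, alpha = 0.05) {
  tf <- paired_t_field(sample_a, sample_b)
  if (tf$degenerate) {
    warning("degenerate (zero-variance) difference field; reporting no ",
            "significant clusters")
    res <- list(t = tf$t, df = tf$df, fwhm = NA_real_, alpha = alpha,
                t_critical = Inf, clusters = list(), significant = FALSE,
                degenerate = TRUE)
    return(structure(res, class = "spm_result"))
  }
  fwhm <- estimate_fwhm(tf$residuals)
  tcrit <- rft_threshold(alpha, tf$df, length(tf$t), fwhm)
  cl <- field_clusters(abs(tf$t) > tcrit)
  structure(list(t = tf$t, df = tf$df, fwhm = fwhm, alpha = alpha,
                 t_critical = tcrit, clusters = cl,
                 significant = length(cl) > 0, degenerate = FALSE),
            class = "spm_result")
}

field_clusters <- function(above) {
  if (!any(above)) return(list())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  Map(function(s, e) c(from = s, to = e), starts[r$values], ends[r$values])
}

#' Total number of nodes inside significant SPM clusters
#' @param x An `spm_result`.
#' @return Integer count of suprathreshold nodes.
#' @export
significant_nodes <- function(x) {
  if (!length(x$clusters)) return(0L)
  sum(vapply(x$clusters, function(cl) cl[["to"]] - cl[["from"]] + 1L, 1L))
}

#' @export
print.spm_result <- function(x, ...) {
  cat(sprintf("SPM paired t-test: df = %d, FWHM = %.1f nodes, t* = %.3f\n",
              x$df, x$fwhm, x$t_critical))
  if (x$significant) {
    cat(sprintf("  %d significant cluster(s): %s\n", length(x$clusters),
                paste(vapply(x$clusters, function(cl)
                  sprintf("%d-%d%%", cl[["from"]] - 1L, cl[["to"]] - 1L),
                  ""), collapse = ", ")))
  } else cat("  no significant clusters\n")
  invisible(x)
}

#' @export
plot.spm_result <- function(x, xlab = "% stance", ylab = "SPM t", ...) {
  q <- seq_along(x$t) - 1
  ylim <- range(c(x$t, x$t_critical, -x$t_critical), finite = TRUE)
  plot(q, x$t, type = "l", lwd = 2, xlab = xlab, ylab = ylab, ylim = ylim,
       ...)
  if (is.finite(x$t_critical))
    abline(h = c(-x$t_critical, x$t_critical), lty = 2)
  for (cl in x$clusters)
    rect(cl[["from"]] - 1L, ylim[1], cl[["to"]] - 1L, ylim[2],
         col = adjustcolor("red", 0.25), border = NA)
  invisible(x)
}

#' Subject-level SPM on a fixed number of sampled steps
#'
#' Samples `n_steps` matched (prediction, measurement) step pairs without
#' replacement using `seed` — keeping the statistical power comparable to a
#' cohort-level test with the same J — and runs [spm_paired_test()] on them.
#' If fewer steps are available, all are used with a warning.
#'
#' @param pred,obs `n x 101` matrices of predicted and measured curves of
#'   one component for one subject/condition.
#' @param n_steps Number of steps to sample (default 18).
#' @param seed Integer seed for the step sampling.
#' @param alpha Significance level.
#' @return An `spm_result`; the selected step indices are attached as
#'   attribute `"steps_used"`.
#' @export
subject_level_spm <- function(pred, obs, n_steps = 18, seed = 1L,
                              alpha = 0.05) {
  stopifnot(all(dim(pred) == dim(obs)))
  n <- nrow(pred)
  if (n < n_steps) {
    warning(sprintf("only %d steps available; using all of them", n))
    idx <- seq_len(n)
  } else {
    idx <- with_seed(seed, sort(sample.int(n, n_steps)))
  }
  out <- spm_paired_test(pred[idx, , drop = FALSE], obs[idx, , drop = FALSE],
                         alpha)
  attr(out, "steps_used") <- idx
  out
}

# ---- simulation utilities ---------------------------------------------------

#' Generate smooth unit-variance Gaussian 1D fields
#'
#' White Gaussian noise circularly convolved with a Gaussian kernel of the
#' requested FWHM and rescaled to unit variance: the stationary smooth null
#' fields used for validating the RFT machinery.
#'
#' @param J Number of curves.
#' @param n_nodes Field length.
#' @param fwhm Kernel full width at half maximum, in nodes.
#' @return `J x n_nodes` matrix.
#' @export
smooth_gaussian_field <- function(J, n_nodes = 101, fwhm = 10) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  x <- matrix(rnorm(J * n_nodes), J, n_nodes)
  if (fwhm <= 0) return(x)
  d <- c(0:(n_nodes %/% 2), -((n_nodes - n_nodes %/% 2 - 1):1))
  k <- exp(-d^2 / (2 * sigma^2))
  K <- stats::fft(k / sum(k))
  sm <- t(apply(x, 1, function(row)
    Re(stats::fft(stats::fft(row) * K, inverse = TRUE)) / n_nodes))
  sm / sqrt(sum((k / sum(k))^2))   # restore unit marginal variance
}

# Permutation (sign-flip) estimate of the max-|t| critical value for paired
# differences; the independent oracle the RFT threshold is validated against.
maxt_perm_threshold <- function(d, n_perm = 10000, alpha = 0.05) {
  J <- nrow(d)
  S <- matrix(sample(c(-1, 1), n_perm * J, replace = TRUE), n_perm, J)
  M <- S %*% d / J
  Q <- matrix(colSums(d^2), n_perm, ncol(d), byrow = TRUE)
  s2 <- pmax(Q - J * M^2, 0) / (J - 1)
  tfield <- M / sqrt(s2 / J)
  mx <- apply(abs(tfield), 1, max)
  unname(quantile(mx, 1 - alpha, type = 7))
}
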