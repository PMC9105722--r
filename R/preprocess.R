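## Preprocessing: raw dual-rate trials -> aligned, stance-segmented,
## 101-node steps with mass-normalized region curves and gravity-frame GRFs.

# ---- step container ---------------------------------------------------------

#' Container for time-normalized steps
#'
#' Holds `n` stance phases, each with five mass-normalized pressure-region
#' curves and two GRF targets (body weights) on a common 101-node grid
#' (0-100% of stance), plus per-step metadata.
#'
#' @param pr Numeric array `n x 5 x 101` of mass-normalized region pressures.
#' @param vert,ap Numeric matrices `n x 101`, GRFs in body weights
#'   (propulsion positive for `ap`).
#' @param meta Data frame with one row per step: `subject_id`, `mass`,
#'   `speed`, `slope`, `foot`, `stance_duration`.
#' @return An object of class `step_dataset`.
#' @export
step_dataset <- function(pr, vert, ap, meta) {
  n <- nrow(meta)
  stopifnot(length(dim(pr)) == 3, dim(pr)[1] == n, dim(pr)[2] == 5,
            dim(pr)[3] == 101, nrow(vert) == n, ncol(vert) == 101,
            nrow(ap) == n, ncol(ap) == 101)
  need <- c("subject_id", "mass", "speed", "slope", "foot", "stance_duration")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("`meta` is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  rownames(meta) <- NULL
  structure(list(pr = pr, vert = vert, ap = ap, meta = meta),
            class = "step_dataset")
}

#' @export
print.step_dataset <- function(x, ...) {
  m <- x$meta
  cat(sprintf("step_dataset: %d steps, %d subjects, %d conditions\n",
              nrow(m), length(unique(m$subject_id)),
              nrow(unique(m[, c("speed", "slope")]))))
  invisible(x)
}

#' @export
`[.step_dataset` <- function(x, i, ...) {
  step_dataset(x$pr[i, , , drop = FALSE], x$vert[i, , drop = FALSE],
               x$ap[i, , drop = FALSE], x$meta[i, , drop = FALSE])
}

#' Number of steps in a step dataset
#' @param x A `step_dataset`.
#' @return Integer step count.
#' @export
n_steps <- function(x) nrow(x$meta)

#' Combine step datasets
#' @param ... `step_dataset` objects.
#' @return A single combined `step_dataset`.
#' @export
bind_steps <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "step_dataset"))
    parts <- parts[[1]]
  pr <- do.call(abind3, lapply(parts, `[[`, "pr"))
  step_dataset(pr,
               do.call(rbind, lapply(parts, `[[`, "vert")),
               do.call(rbind, lapply(parts, `[[`, "ap")),
               do.call(rbind, lapply(parts, `[[`, "meta")))
}

abind3 <- function(...) {
  mats <- list(...)
  ns <- vapply(mats, function(a) dim(a)[1], 1L)
  out <- array(0, c(sum(ns), dim(mats[[1]])[2], dim(mats[[1]])[3]))
  at <- 0L
  for (a in mats) {
    if (dim(a)[1] > 0) out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

# ---- elementary operations --------------------------------------------------

#' Rotate treadmill-frame GRFs into the gravity frame
#'
#' On a sloped treadmill the force plate measures forces in a belt-aligned
#' frame.  This applies the planar rotation by the slope angle about the
#' medial-lateral axis so that the vertical component is parallel to
#' gravity; per-sample vector magnitudes are preserved.
#'
#' @param grf Numeric matrix with columns (belt-normal, belt-parallel) or
#'   (belt-normal, belt-parallel, medial-lateral).
#' @param slope_deg Slope in degrees (negative = decline).
#' @return Matrix of the same shape; columns 1-2 are now (vertical,
#'   anterior-posterior) in the gravity frame.
#' @export
rotate_grf_to_gravity <- function(grf, slope_deg) {
  if (is.vector(grf)) grf <- matrix(grf, ncol = length(grf))
  if (!all(is.finite(grf[, 1:2])) || !is.finite(slope_deg))
    stop("non-finite input to rotate_grf_to_gravity", call. = FALSE)
  theta <- slope_deg * pi / 180
  out <- grf
  out[, 1] <- grf[, 1] * cos(theta) - grf[, 2] * sin(theta)
  out[, 2] <- grf[, 1] * sin(theta) + grf[, 2] * cos(theta)
  out
}

#' Zero-phase low-pass Butterworth filter
#'
#' Applies the squared magnitude response of an order-`order` Butterworth
#' low-pass (the effective response of a forward-backward pass) with exactly
#' zero phase.  The filter is applied in the frequency domain using the
#' analytic response `|H(f)|^2 = 1 / (1 + (f/cutoff)^(2*order))`, after
#' odd-reflection padding of the signal, which gives unit DC gain and no
#' start-up transients.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate (Hz); must exceed twice the cutoff.
#' @param cutoff Cutoff frequency (Hz).
#' @param order Single-pass filter order.
#' @return Filtered vector, same length as `x`.
#' @export
lowpass_filter <- function(x, fs, cutoff = 50, order = 3) {
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  if (fs <= 2 * cutoff)
    stop("`fs` must exceed twice the cutoff frequency", call. = FALSE)
  n <- length(x)
  pad <- min(n - 1L, as.integer(ceiling(6 * fs / cutoff)))
  if (n < 4L) stop("signal too short to filter", call. = FALSE)
  xe <- c(2 * x[1] - x[(pad + 1):2],
          x,
          2 * x[n] - x[(n - 1):(n - pad)])
  m <- length(xe)
  f <- seq(0, m - 1) / m * fs
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  H <- 1 / (1 + (f / cutoff)^(2 * order))   # squared single-pass magnitude
  y <- Re(stats::fft(stats::fft(xe) * H, inverse = TRUE)) / m
  y[(pad + 1):(pad + n)]
}

#' Recover the integer lag between pressure and force-plate streams
#'
#' Low-passes and downsamples the vertical GRF to the pressure rate, then
#' finds the integer lag (in pressure-rate samples) maximizing the normalized
#' cross-correlation over the synchronization-jump window.  Fails explicitly
#' when the correlation peak is below `min_corr` (ambiguous alignment).
#'
#' @param grf_vert Vertical GRF at `fs_grf` (gravity frame, N or BW).
#' @param pressure_total Per-frame total insole pressure at `fs_pressure`.
#' @param fs_grf,fs_pressure Sampling rates (Hz).
#' @param max_lag Largest |lag| searched, in pressure-rate samples.
#' @param jump_window_s Length of the window (s) containing the jumps.
#' @param min_corr Confidence floor for the correlation peak.
#' @return Integer lag; positive means the pressure stream starts late.  The
#'   peak correlation is attached as attribute `"peak_corr"`.
#' @export
synchronize_streams <- function(grf_vert, pressure_total, fs_grf,
                                fs_pressure, max_lag = 100L,
                                jump_window_s = 5, min_corr = 0.6) {
  ratio <- fs_grf / fs_pressure
  # force-plate noise is negligible at jump scale, so the GRF side is only
  # band-limited for decimation; the pressure side is left raw — with
  # (near-)white sensor noise the plain cross-correlation is the
  # maximum-likelihood lag estimator
  g <- lowpass_filter(grf_vert, fs_grf, cutoff = min(50, fs_pressure / 2.5))
  idx <- round(seq(1, length(g), by = ratio))
  idx <- idx[idx <= length(g)]
  g_ds <- g[idx]
  nw <- min(length(g_ds), round(jump_window_s * fs_pressure) + max_lag)
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(l) {
    k <- seq_len(nw)
    kp <- k; kg <- k - l
    ok <- kg >= 1 & kg <= length(g_ds) & kp <= length(pressure_total)
    if (sum(ok) < 10) return(NA_real_)
    suppressWarnings(cor(pressure_total[kp[ok]], g_ds[kg[ok]]))
  }, 1.0)
  if (all(is.na(cc))) stop("streams too short to synchronize", call. = FALSE)
  best <- which.max(cc)
  if (cc[best] < min_corr)
    stop(sprintf(
      "ambiguous synchronization: peak correlation %.2f below floor %.2f",
      cc[best], min_corr), call. = FALSE)
  # refine by parabolic interpolation through the peak and its neighbours:
  # the vertex is much more stable under noise than the raw argmax when two
  # adjacent lags are near-tied
  lag <- lags[best]
  if (best > 1 && best < length(cc) && !anyNA(cc[(best - 1):(best + 1)])) {
    v <- cc[(best - 1):(best + 1)]
    denom <- v[1] - 2 * v[2] + v[3]
    if (denom < 0) {
      vertex <- lags[best] + 0.5 * (v[1] - v[3]) / denom
      lag <- as.integer(round(max(min(vertex, max(lags)), min(lags))))
    }
  }
  structure(lag, peak_corr = cc[best])
}

#' Detect stance phases from the vertical GRF
#'
#' Finds half-open sample intervals \[on, off) where the (already filtered)
#' vertical GRF first exceeds and then falls below a force threshold.
#' Sub-threshold dips shorter than `min_flight_s` are bridged, candidate
#' stances shorter than `min_stance_s` are discarded, and intervals starting
#' before `analysis_start_s` (quiet stance, synchronization jumps, treadmill
#' spin-up) are excluded.
#'
#' @param grf_vert Filtered vertical GRF (N).
#' @param fs Sampling rate (Hz).
#' @param threshold_N Force threshold (N); 20 N is the usual force-plate
#'   convention.
#' @param min_stance_s,min_flight_s Debouncing durations (s).
#' @param analysis_start_s Ignore intervals beginning before this time (s).
#' @param min_peak_N Candidate stances whose peak force stays below this
#'   floor are rejected as noise excursions (running stances peak well
#'   above 1000 N).
#' @return Integer matrix with columns `on`, `off` (1-based, half-open),
#'   sorted and non-overlapping; zero rows when no steps are found.
#' @export
detect_steps <- function(grf_vert, fs, threshold_N = 20, min_stance_s = 0.1,
                         min_flight_s = 0.05, analysis_start_s = 0,
                         min_peak_N = 100) {
  above <- grf_vert > threshold_N
  if (!any(above))
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("on", "off"))))
  r <- rle(above)
  # bridge short sub-threshold dips (debouncing)
  short_gap <- !r$values & r$lengths < min_flight_s * fs
  inner <- which(short_gap)
  inner <- inner[inner > 1 & inner < length(r$values)]
  r$values[inner] <- TRUE
  r <- rle(inverse.rle(r))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_stance_s * fs
  out <- cbind(on = starts[keep], off = ends[keep] + 1L)
  out <- out[out[, "on"] > analysis_start_s * fs, , drop = FALSE]
  peaks <- vapply(seq_len(nrow(out)), function(k)
    max(grf_vert[out[k, 1]:(out[k, 2] - 1L)]), 1.0)
  out[peaks >= min_peak_N, , drop = FALSE]
}

#' Sum a 99-sensor pressure frame into five regions
#'
#' @param pressure Numeric vector of length 99, or a `T x 99` matrix.
#' @param region_map Integer vector of length 99 assigning each sensor to a
#'   region 1-5; see [default_region_map()].
#' @return Numeric vector of 5 region sums, or a `T x 5` matrix.  Region sums
#'   always add up to the total frame sum.
#' @export
sum_regions <- function(pressure, region_map = default_region_map()) {
  if (is.vector(pressure)) {
    if (length(pressure) != length(region_map))
      stop(sprintf("expected %d sensor values, got %d", length(region_map),
                   length(pressure)), call. = FALSE)
    return(drop(rowsum(pressure, region_map)))
  }
  if (ncol(pressure) != length(region_map))
    stop(sprintf("expected %d sensor columns, got %d", length(region_map),
                 ncol(pressure)), call. = FALSE)
  t(rowsum(t(pressure), region_map))
}

#' Linearly interpolate a curve onto n equally spaced nodes
#'
#' @param curve Numeric vector (length >= 2) sampled uniformly over the
#'   stance interval.
#' @param n Number of output nodes (101 = 0-100% of stance).
#' @return Numeric vector of length `n`; endpoints are preserved exactly.
#' @export
time_normalize <- function(curve, n = 101) {
  m <- length(curve)
  if (m < 2) stop("`curve` must have at least 2 samples", call. = FALSE)
  approx(seq(0, 1, length.out = m), curve, xout = seq(0, 1, length.out = n),
         method = "linear")$y
}

# interpolate (times, values) onto n nodes spanning [t0, t1]
interp_to_phase <- function(times, values, t0, t1, n = 101) {
  approx(times, values, xout = seq(t0, t1, length.out = n), method = "linear",
         rule = 2)$y
}

# ---- step extraction --------------------------------------------------------

#' Extract time-normalized steps from a raw trial
#'
#' The composite preprocessing operation: rotates GRFs into the gravity
#' frame, applies the zero-phase 50 Hz Butterworth to the force channels,
#' synchronizes the pressure stream via the jump cross-correlation (unless
#' `lag` is supplied), segments stances from the filtered vertical GRF (or
#' uses `intervals`), then for every stance sums the pressure frames into
#' five regions, divides by body mass, converts forces to body weights, and
#' linearly interpolates all seven channels onto 101 nodes.
#'
#' Steps whose pressure window falls outside the recording after lag
#' correction are dropped; the number of dropped steps is recorded in
#' attribute `"dropped"`.
#'
#' @param trial A `grf_trial` (see [assemble_trial()] / [read_trial()]).
#' @param intervals Optional `k x 2` matrix of stance intervals (GRF-rate,
#'   1-based, half-open); default: detected from the filtered vertical GRF.
#' @param lag Optional known pressure lag (pressure-rate samples); default:
#'   estimated with [synchronize_streams()].
#' @param cutoff,order Butterworth settings for the GRF channels.
#' @param threshold_N,min_stance_s,min_flight_s Segmentation settings.
#' @param analysis_start_s Steps beginning before this time are discarded;
#'   defaults to the trial's own value (25 s is the steady-state convention
#'   for real recordings).
#' @param region_map Sensor-to-region assignment.
#' @return A [step_dataset()].
#' @export
extract_steps <- function(trial, intervals = NULL, lag = NULL, cutoff = 50,
                          order = 3, threshold_N = 20, min_stance_s = 0.1,
                          min_flight_s = 0.05, analysis_start_s = NULL,
                          region_map = default_region_map()) {
  stopifnot(inherits(trial, "grf_trial"))
  fs_g <- trial$fs_grf; fs_p <- trial$fs_pressure
  analysis_start_s <- analysis_start_s %||% trial$analysis_start_s %||% 0
  grf_g <- rotate_grf_to_gravity(trial$grf, trial$condition$slope)
  vert <- lowpass_filter(grf_g[, 1], fs_g, cutoff, order)
  ap <- lowpass_filter(grf_g[, 2], fs_g, cutoff, order)
  if (is.null(lag)) {
    lag <- synchronize_streams(grf_g[, 1], rowSums(trial$pressure),
                               fs_g, fs_p)
  }
  lag <- as.integer(lag)
  if (is.null(intervals)) {
    intervals <- detect_steps(vert, fs_g, threshold_N, min_stance_s,
                              min_flight_s, analysis_start_s)
  }
  mass <- trial$subject$mass
  regions <- sum_regions(trial$pressure, region_map) / mass
  # pressure frame k holds the signal at time (k - 1 - lag) / fs_p
  t_frames <- (seq_len(nrow(regions)) - 1 - lag) / fs_p

  n <- nrow(intervals)
  keep <- logical(n)
  pr <- array(0, c(n, 5, 101))
  vmat <- matrix(0, n, 101); amat <- matrix(0, n, 101)
  dur <- numeric(n)
  for (k in seq_len(n)) {
    on <- intervals[k, 1]; off <- intervals[k, 2]
    t0 <- (on - 1) / fs_g; t1 <- (off - 1) / fs_g
    f_in <- which(t_frames >= t0 - 1 / fs_p & t_frames <= t1 + 1 / fs_p)
    if (length(f_in) < 2 || min(f_in) < 1 || max(f_in) > nrow(regions)) next
    keep[k] <- TRUE
    dur[k] <- t1 - t0
    for (r in 1:5)
      pr[k, r, ] <- interp_to_phase(t_frames[f_in], regions[f_in, r], t0, t1)
    vmat[k, ] <- pmax(0, time_normalize(vert[on:(off - 1)]) / (mass * .GRAVITY))
    amat[k, ] <- time_normalize(ap[on:(off - 1)]) / (mass * .GRAVITY)
  }
  pr[pr < 0] <- 0
  meta <- data.frame(
    subject_id = trial$subject$subject_id %||% "S?",
    mass = mass,
    speed = trial$condition$speed,
    slope = trial$condition$slope,
    foot = trial$foot,
    stance_duration = dur,
    stringsAsFactors = FALSE)[seq_len(n), , drop = FALSE]
  out <- step_dataset(pr[keep, , , drop = FALSE], vmat[keep, , drop = FALSE],
                      amat[keep, , drop = FALSE],
                      meta[keep, , drop = FALSE])
  attr(out, "dropped") <- sum(!keep)
  attr(out, "lag_used") <- lag
  out
}

#' Preprocess every trial of a cohort into one step dataset
#'
#' @param cohort A `grf_cohort` (or plain list of `grf_trial`s).
#' @param ... Passed to [extract_steps()].
#' @param verbose Print per-stage accounting (trials read, steps kept,
#'   steps dropped).
#' @return A [step_dataset()] with attribute `"dropped"` (total).
#' @export
preprocess_cohort <- function(cohort, ..., verbose = FALSE) {
  trials <- if (inherits(cohort, "grf_cohort")) cohort$trials else cohort
  parts <- lapply(trials, extract_steps, ...)
  dropped <- sum(vapply(parts, function(p) attr(p, "dropped") %||% 0L, 0L))
  out <- bind_steps(parts)
  attr(out, "dropped") <- dropped
  if (verbose)
    message(sprintf("%d trials -> %d steps (%d dropped)",
                    length(trials), n_steps(out), dropped))
  out
}
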