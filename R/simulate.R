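## Synthetic graded-running cohort generator.
##
## Every downstream stage (synchronization, segmentation, model fitting, SPM)
## is testable against the ground truth this module records: true stream lags,
## stance intervals, noise-free 101-node GRF curves and the planted
## pressure-to-force mapping.

# ---- study conditions -------------------------------------------------------

#' Treadmill speed/slope conditions of the graded-running protocol
#'
#' The eleven combinations used throughout the package: level running at 2.6,
#' 3.0, 3.4 and 3.8 m/s, six degrees uphill at 2.6, 2.8 and 3.0 m/s, and six
#' degrees downhill at 2.6, 2.8, 3.0 and 3.4 m/s.
#'
#' @return A data frame with columns `speed` (m/s) and `slope` (degrees,
#'   negative = decline), one row per condition.
#' @export
#' @examples
#' graded_conditions()
graded_conditions <- function() {
  data.frame(
    speed = c(2.6, 3.0, 3.4, 3.8,  2.6, 2.8, 3.0,  2.6, 2.8, 3.0, 3.4),
    slope = c(0, 0, 0, 0,  6, 6, 6,  -6, -6, -6, -6)
  )
}

condition_key <- function(speed, slope) {
  sprintf("v%.1f_s%+.0f", speed, slope)
}

# ---- configuration ----------------------------------------------------------

#' Configuration for the synthetic cohort simulator
#'
#' @param n_subjects Number of subjects.
#' @param conditions Data frame with columns `speed` (m/s, > 0) and `slope`
#'   (degrees, within \[-15, 15\]). Defaults to [graded_conditions()].
#' @param steps_per_trial Stance phases rendered per trial and foot.
#' @param fs_grf Force-plate sampling rate (Hz).
#' @param fs_pressure Insole sampling rate (Hz).
#' @param lag_samples Integer offset of the pressure stream relative to the
#'   force plate, in pressure-rate samples.  A scalar or one value per trial;
#'   `NULL` draws one lag per trial uniformly from -30..30.
#' @param noise_sd_pressure Per-sensor Gaussian noise SD (kPa); pressures are
#'   clipped at zero.
#' @param noise_sd_grf Gaussian noise SD added to each force channel (N).
#' @param mapping_mode `"linear"` for the exact planted linear
#'   pressure-to-force mapping, `"saturating"` for a smooth concave
#'   compression of each region so that no linear model is exact.
#' @param footstrike_policy `"fixed_rearfoot"`, `"fixed_forefoot"`, or
#'   `"slope_dependent"` (subjects keep their habitual pattern on level
#'   ground; uphill-switching subjects move to a forefoot strike on inclines
#'   and every subject rearfoot-strikes on declines).
#' @param idiosyncratic_gains Named numeric vector of per-subject force gains
#'   (subject ids `"S01"`, ...), or a scalar applied to all subjects.  A gain
#'   g scales a subject's measured GRFs by g while leaving the plantar
#'   pressure unchanged, emulating a runner whose pressure-to-force
#'   relationship deviates from the cohort's.
#' @param analysis_start_s Steps beginning before this time (s) are discarded
#'   during preprocessing; the simulated pre-roll (quiet stance + three
#'   synchronization jumps) ends at 4.5 s.
#' @param seed Integer seed; fully determines the simulated cohort.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 18,
                       conditions = graded_conditions(),
                       steps_per_trial = 30,
                       fs_grf = 2400,
                       fs_pressure = 100,
                       lag_samples = NULL,
                       noise_sd_pressure = 0.5,
                       noise_sd_grf = 2,
                       mapping_mode = c("linear", "saturating"),
                       footstrike_policy = c("slope_dependent",
                                             "fixed_rearfoot",
                                             "fixed_forefoot"),
                       idiosyncratic_gains = 1.0,
                       analysis_start_s = 4.5,
                       seed = 1L) {
  mapping_mode <- match.arg(mapping_mode)
  footstrike_policy <- match.arg(footstrike_policy)
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop("`n_subjects` must be a positive count", call. = FALSE)
  if (!is.data.frame(conditions) ||
      !all(c("speed", "slope") %in% names(conditions)))
    stop("`conditions` needs columns `speed` and `slope`", call. = FALSE)
  if (any(conditions$speed <= 0)) stop("speeds must be positive", call. = FALSE)
  if (any(abs(conditions$slope) > 15))
    stop("slopes outside [-15, 15] degrees are not supported", call. = FALSE)
  if (steps_per_trial < 1) stop("`steps_per_trial` must be >= 1", call. = FALSE)
  stopifnot_scalar_number(fs_grf, "fs_grf", positive = TRUE)
  stopifnot_scalar_number(fs_pressure, "fs_pressure", positive = TRUE)
  if (noise_sd_pressure < 0 || noise_sd_grf < 0)
    stop("noise standard deviations must be >= 0", call. = FALSE)
  structure(list(
    n_subjects = as.integer(n_subjects),
    conditions = conditions,
    steps_per_trial = as.integer(steps_per_trial),
    fs_grf = fs_grf,
    fs_pressure = fs_pressure,
    lag_samples = lag_samples,
    noise_sd_pressure = noise_sd_pressure,
    noise_sd_grf = noise_sd_grf,
    mapping_mode = mapping_mode,
    footstrike_policy = footstrike_policy,
    idiosyncratic_gains = idiosyncratic_gains,
    analysis_start_s = analysis_start_s,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic graded-running cohort configuration\n")
  cat(sprintf("  %d subjects x %d conditions, %d steps/trial/foot\n",
              x$n_subjects, nrow(x$conditions), x$steps_per_trial))
  cat(sprintf("  rates: GRF %g Hz, pressure %g Hz; mapping: %s; seed %d\n",
              x$fs_grf, x$fs_pressure, x$mapping_mode, x$seed))
  invisible(x)
}

# ---- planted pressure-to-force mapping -------------------------------------

#' Planted linear mapping between pressure regions and GRFs
#'
#' The simulator constructs its five region curves so that, in linear mapping
#' mode, `GRF_vert = sum(A[i] * PR[i] / mass)` and
#' `GRF_ap = sum(B[i] * PR[i] / mass)` hold exactly at every instant (times
#' any subject-specific idiosyncratic gain).  These are the coefficients a
#' correctly implemented least-squares fit must recover.
#'
#' @return List with numeric vectors `A` and `B` of length 5 (heel, midfoot,
#'   medial forefoot, lateral forefoot, toe).
#' @export
planted_coefficients <- function() {
  list(A = c(1.2, 1.6, 1.8, 1.8, 1.0),
       B = c(-2.0, -0.6, 0.4, 0.4, 2.0))
}

# Region weights for the five waveform lobes (impact, active, braking,
# propulsion, medial/lateral forefoot asymmetry).  Columns 1-4 solve
# A' w = a, B' w = b for the targets (a,b) = (1,-0.5), (1,0), (0.6,-1),
# (0.5,1), so the planted coefficients reproduce the lobe sums exactly.
# The asymmetry column (0,0,1,-1,0) lies in the null space of both A and B:
# it perturbs the two forefoot regions without changing either GRF, giving
# the five region curves full rank so the planted coefficients are the
# unique least-squares solution.  Rows: heel, midfoot, forefoot x2, toe.
lobe_region_weights <- function() {
  w_imp <- solve(matrix(c(1.2, 1.6, -2.0, -0.6), 2, byrow = TRUE), c(1, -0.5))
  s <- 1 / (1.6 * 2 / 3 + 1.8)      # midfoot/forefoot split with B' w = 0
  W <- matrix(0, 5, 6,
              dimnames = list(NULL,
                              c("imp", "act", "br", "pr", "asym", "mshift")))
  W[1:2, "imp"] <- w_imp
  W[2:4, "act"] <- c(2 / 3 * s, s / 2, s / 2)
  W[1, "br"] <- 0.5
  W[5, "pr"] <- 0.5
  W[3:4, "asym"] <- c(1, -1)
  # second null-space direction (heel/midfoot/toe load shift): A' n = B' n = 0
  n12 <- solve(matrix(c(1.2, 1.6, -2.0, -0.6), 2, byrow = TRUE), c(-1, -2))
  W[c(1, 2, 5), "mshift"] <- c(n12, 1)
  W
}

# Concave per-region compression used in "saturating" mapping mode, in
# mass-normalized pressure units.  Scales chosen near typical region peaks so
# the compression is strong enough that no linear model fits exactly.
SAT_SCALE <- c(0.18, 0.50, 0.20, 0.20, 0.10)

saturate_regions <- function(p) {
  # p: T x 5 mass-normalized region curves
  S <- matrix(SAT_SCALE, nrow(p), 5, byrow = TRUE)
  S * tanh(p / S)
}

# ---- waveform model ---------------------------------------------------------

raised_bump <- function(phase, center, halfwidth) {
  u <- (phase - center) / halfwidth
  out <- numeric(length(phase))
  idx <- abs(u) < 1
  out[idx] <- 0.5 * (1 + cos(pi * u[idx]))
  out
}

# Lobe amplitudes (BW) for one stance as a function of condition, foot strike
# and an optional multiplicative jitter (one value per lobe).  The asymmetry
# amplitude stays below ~8.5% of the active amplitude so that the lateral
# forefoot region (which receives it with a negative weight) never goes
# negative.
lobe_amplitudes <- function(speed, slope, footstrike, jitter = rep(1, 6)) {
  sp <- (speed - 2.6) / 1.2
  act <- (2.0 + 0.8 * sp) * (1 + 0.004 * slope)
  imp <- if (footstrike == "rearfoot") (0.75 + 0.15 * sp) * (1 - 0.015 * slope) else 0
  beta <- 0.28 + 0.10 * sp
  br <- beta * (1 - 0.035 * slope)
  pr <- beta * (1 + 0.035 * slope)
  c(imp = imp * jitter[1], act = act * jitter[2], br = br * jitter[3],
    pr = pr * jitter[4],
    asym = 0.06 * act * min(jitter[5], 1.4),
    mshift = 0.02 * act * min(jitter[6], 3))
}

lobe_curves <- function(phase, amps) {
  cbind(imp = amps[["imp"]] * raised_bump(phase, 0.12, 0.10),
        act = amps[["act"]] * sin(pi * phase)^2,
        br  = amps[["br"]]  * raised_bump(phase, 0.27, 0.20),
        pr  = amps[["pr"]]  * raised_bump(phase, 0.73, 0.20),
        asym = amps[["asym"]] * raised_bump(phase, 0.50, 0.25),
        mshift = amps[["mshift"]] * sin(pi * phase)^2)
}

#' Synthesize noise-free GRF curves for one stance phase
#'
#' Builds the vertical and anterior-posterior ground reaction force of a
#' single stance from four raised-cosine lobes (impact, active, braking,
#' propulsion).  The vertical force is zero at touchdown and toe-off and its
#' active peak grows with running speed; the A/P force shows a braking
#' (negative) lobe before mid-stance and a propulsive (positive) lobe after
#' it, with uphill slopes shifting area towards propulsion and downhill
#' slopes towards braking.  Rearfoot strikers receive an early impact
#' transient; forefoot strikers do not.
#'
#' @param condition List or one-row data frame with `speed` (m/s) and `slope`
#'   (degrees).
#' @param subject List with at least `footstrike` (`"rearfoot"` or
#'   `"forefoot"`) and optionally `idiosyncratic_gain` (default 1).
#' @param phase_grid Numeric vector of stance phases in \[0, 1\].
#' @param jitter Optional multiplicative jitter per lobe (length 4).
#' @return List with `vert` and `ap` (body weights, same length as
#'   `phase_grid`).  The lobe curves used are attached as attribute
#'   `"lobes"` so the exact pressure decomposition can be recovered.
#' @export
#' @examples
#' s <- synth_grf_step(list(speed = 3.0, slope = 0),
#'                     list(footstrike = "rearfoot"), seq(0, 1, length = 101))
#' range(s$vert)
synth_grf_step <- function(condition, subject, phase_grid,
                           jitter = rep(1, 6)) {
  if (any(phase_grid < 0 | phase_grid > 1))
    stop("`phase_grid` must lie in [0, 1]", call. = FALSE)
  gain <- subject$idiosyncratic_gain %||% 1
  amps <- lobe_amplitudes(condition$speed, condition$slope,
                          subject$footstrike, jitter)
  d <- lobe_curves(phase_grid, amps)
  W <- lobe_region_weights()
  p <- d %*% t(W)                       # T x 5 mass-normalized regions
  ab <- planted_coefficients()
  vert <- gain * drop(p %*% ab$A)
  ap <- gain * drop(p %*% ab$B)
  structure(list(vert = vert, ap = ap), lobes = d)
}

#' Region pressure curves consistent with given GRF curves
#'
#' Inverts the planted mapping: returns five nonnegative region pressure
#' curves `PR` (in kPa-scale units) such that, in linear mode,
#' `vert == PR %*% A / mass` and `ap == PR %*% B / mass` exactly, with
#' `A`/`B` from [planted_coefficients()].  When the curves carry the lobe
#' decomposition produced by [synth_grf_step()] the exact region split is
#' used; otherwise a minimum-norm per-node solution is computed, and the
#' function fails if that solution would require negative pressure.
#'
#' In `"saturating"` mode each mass-normalized region curve is compressed
#' through a smooth concave map (`S * tanh(p / S)`) before being scaled back
#' to raw pressure, so no linear model reproduces the forces exactly.
#'
#' @param vert_BW,ap_BW GRF curves in body weights on a common grid.  Either
#'   the output of [synth_grf_step()] (preferred) or arbitrary curves.
#' @param subject List with `mass` (kg) and optionally `idiosyncratic_gain`.
#' @param mapping_mode `"linear"` or `"saturating"`.
#' @return T x 5 matrix of raw region pressures, all `>= 0`.
#' @export
pressure_from_force <- function(vert_BW, ap_BW, subject,
                                mapping_mode = c("linear", "saturating")) {
  mapping_mode <- match.arg(mapping_mode)
  mass <- subject$mass %||% stop("`subject$mass` is required", call. = FALSE)
  gain <- subject$idiosyncratic_gain %||% 1
  lobes <- attr(vert_BW, "lobes")
  if (is.list(vert_BW) && !is.null(attr(vert_BW, "lobes")))
    lobes <- attr(vert_BW, "lobes")
  if (is.list(vert_BW)) {               # accept synth_grf_step() output
    step <- vert_BW
    vert_BW <- step$vert
    ap_BW <- step$ap
  }
  if (length(vert_BW) != length(ap_BW))
    stop("`vert_BW` and `ap_BW` must share a grid", call. = FALSE)
  if (!is.null(lobes)) {
    p <- lobes %*% t(lobe_region_weights())   # exact decomposition, gain-free
  } else {
    ab <- planted_coefficients()
    M <- rbind(ab$A, ab$B)
    pinv <- t(M) %*% solve(M %*% t(M))
    p <- cbind(vert_BW, ap_BW) %*% t(pinv) / gain
    if (any(p < -1e-9))
      stop("requested GRF curves are infeasible: the mapping would need ",
           "negative region pressure", call. = FALSE)
    p[p < 0] <- 0
  }
  if (mapping_mode == "saturating") p <- saturate_regions(p)
  unname(p * mass)
}

# ---- insole sensor layout ---------------------------------------------------

#' Default five-region map for the 99-sensor insole
#'
#' A schematic layout: five proximal-to-distal bands of 22, 20, 20, 20 and 17
#' sensors (heel, midfoot, medial forefoot, lateral forefoot, toes).
#'
#' @return Integer vector of length 99 with region ids 1-5.
#' @export
default_region_map <- function() {
  rep.int(1:5, c(22L, 20L, 20L, 20L, 17L))
}

# Fixed within-region spatial profile (weights sum to 1 per region).
sensor_profiles <- function(region_map = default_region_map()) {
  q <- numeric(length(region_map))
  for (r in unique(region_map)) {
    idx <- which(region_map == r)
    m <- length(idx)
    w <- 1.2 - abs(seq_len(m) - (m + 1) / 2) / ((m + 1) / 2)
    q[idx] <- w / sum(w)
  }
  q
}

# ---- trial assembly ---------------------------------------------------------

# Render one trial's continuous-time mass-normalized region curves and BW
# GRFs on an arbitrary time grid.  `plan` is the per-step schedule made by
# trial_plan().
render_streams <- function(times, plan, subject, condition) {
  p <- matrix(0, length(times), 5)
  vert <- numeric(length(times))
  ap <- numeric(length(times))
  W <- lobe_region_weights()
  ab <- planted_coefficients()
  gain <- subject$idiosyncratic_gain %||% 1
  # pre-roll: quiet stance then three jump bursts.  Flat two-footed
  # landings load the heel and toe bands; the distribution solves
  # A'u = 1, B'u = 0 so the planted linear relation holds during the
  # pre-roll as well, and it maximizes total pressure per BW, which
  # sharpens the synchronization correlation peak.
  u_jump <- numeric(5)
  u_jump[c(1, 5)] <- 1 / (ab$A[1] + ab$A[5])   # B[1] = -B[5] cancels
  pre_bw <- preroll_bw(times)
  p <- p + outer(pre_bw, u_jump)
  vert <- vert + gain * pre_bw
  for (k in seq_len(nrow(plan))) {
    on <- plan$t_on[k]; dur <- plan$dur[k]
    idx <- which(times >= on & times < on + dur)
    if (!length(idx)) next
    phase <- (times[idx] - on) / dur
    d <- lobe_curves(phase, unlist(plan$amps[[k]]))
    pk <- d %*% t(W)
    p[idx, ] <- p[idx, ] + pk
    vert[idx] <- vert[idx] + gain * drop(pk %*% ab$A)
    ap[idx] <- ap[idx] + gain * drop(pk %*% ab$B)
  }
  list(regions = p, vert = vert, ap = ap)
}

# Quiet stance (0.5 BW) followed by three 2.5 BW half-sine jump bursts;
# landing impacts are short (~0.12 s) and separated by ~1 s of near-zero
# load, giving the cross-correlation a sharp, unambiguous peak.
preroll_bw <- function(times) {
  bw <- numeric(length(times))
  ramp <- function(t, t0, t1) pmin(1, pmax(0, (t - t0) / (t1 - t0)))
  stand <- 0.5 * ramp(times, 0.05, 0.2) * (1 - ramp(times, 0.7, 0.85))
  bw <- bw + stand
  for (t0 in c(1.2, 2.2, 3.2)) {
    idx <- which(times >= t0 & times < t0 + 0.10)
    bw[idx] <- bw[idx] + 2.5 * sin(pi * (times[idx] - t0) / 0.10)
  }
  bw
}

trial_plan <- function(config, subject, condition, foot, seed) {
  with_seed(seed, {
    sp <- (condition$speed - 2.6) / 1.2
    cycle <- 0.74 - 0.08 * sp
    stance <- (0.31 - 0.04 * sp) * (1 + 0.005 * condition$slope)
    fs <- effective_footstrike(config$footstrike_policy, subject, condition)
    t0 <- 5.0 + if (foot == "left") cycle / 2 else 0
    n <- config$steps_per_trial
    t_on <- t0 + (seq_len(n) - 1) * cycle + rnorm(n, 0, 0.010)
    dur <- pmax(0.15, stance + rnorm(n, 0, 0.004))
    amps <- lapply(seq_len(n), function(k)
      as.list(lobe_amplitudes(condition$speed, condition$slope, fs,
                              jitter = exp(rnorm(6, 0, c(0.02, 0.02, 0.02,
                                                         0.02, 0.20,
                                                         0.40))))))
    data.frame(t_on = t_on, dur = dur, amps = I(amps),
               footstrike = fs, stringsAsFactors = FALSE)
  })
}

effective_footstrike <- function(policy, subject, condition) {
  switch(policy,
    fixed_rearfoot = "rearfoot",
    fixed_forefoot = "forefoot",
    slope_dependent = {
      if (condition$slope > 0 && isTRUE(subject$uphill_switcher)) "forefoot"
      else if (condition$slope < 0) "rearfoot"
      else subject$footstrike
    })
}

#' Assemble one raw dual-rate trial from a step schedule
#'
#' Renders the stance waveforms at the force-plate rate (treadmill-frame GRFs
#' in newtons) and the insole rate (99 sensor pressures in kPa), prepends the
#' quiet-stance/three-jump pre-roll, applies the configured integer lag to
#' the pressure stream, and adds Gaussian noise.  The returned object records
#' the true lag and the stance intervals both as continuous times and as
#' 20 N-threshold crossings of the low-passed noise-free vertical GRF (the
#' convention [detect_steps()] uses).
#'
#' @param config A [sim_config()].
#' @param subject Subject metadata list (`subject_id`, `mass`, `footstrike`,
#'   `idiosyncratic_gain`, `uphill_switcher`).
#' @param condition List with `speed` and `slope`.
#' @param foot `"left"` or `"right"`.
#' @param lag Integer pressure-stream lag in pressure-rate samples.
#' @param seed Integer seed for this trial's jitter and noise.
#' @return An object of class `grf_trial`.
#' @export
assemble_trial <- function(config, subject, condition, foot = "right",
                           lag = 0L, seed = 1L) {
  plan <- trial_plan(config, subject, condition, foot, seed)
  sp <- (condition$speed - 2.6) / 1.2
  cycle <- 0.74 - 0.08 * sp
  t_end <- max(plan$t_on + plan$dur) + 0.5
  fs_g <- config$fs_grf; fs_p <- config$fs_pressure
  n_g <- ceiling(t_end * fs_g)
  n_p <- round(n_g * fs_p / fs_g)
  if (abs(lag) >= n_p)
    stop("`lag` exceeds the recording length", call. = FALSE)
  t_g <- (seq_len(n_g) - 1) / fs_g
  # pressure frame k holds the signal at time (k - 1 - lag) / fs_p
  t_p <- (seq_len(n_p) - 1 - lag) / fs_p

  sg <- render_streams(t_g, plan, subject, condition)
  spr <- render_streams(pmax(t_p, -1), plan, subject, condition)
  mass <- subject$mass
  # gravity-frame BW -> treadmill-frame newtons
  theta <- condition$slope * pi / 180
  vert_N <- sg$vert * mass * .GRAVITY
  ap_N <- sg$ap * mass * .GRAVITY
  grf <- cbind(vert_N * cos(theta) + ap_N * sin(theta),
               -vert_N * sin(theta) + ap_N * cos(theta),
               0)
  regions <- spr$regions
  if (config$mapping_mode == "saturating") regions <- saturate_regions(regions)
  q <- sensor_profiles()
  rmap <- default_region_map()
  pressure <- (regions * mass)[, rmap] * rep(q, each = nrow(regions))

  # noise-free bookkeeping before noise injection
  vert_clean <- grf[, 1] * cos(theta) - grf[, 2] * sin(theta)
  ap_clean <- grf[, 1] * sin(theta) + grf[, 2] * cos(theta)
  vert_filt <- lowpass_filter(vert_clean, fs_g)
  ap_filt <- lowpass_filter(ap_clean, fs_g)
  thr_int <- threshold_intervals(vert_filt, threshold = 20,
                                 min_len = round(0.1 * fs_g))
  # the ledger lists running steps only, not the pre-roll stance/jumps
  thr_int <- thr_int[thr_int[, "on"] > config$analysis_start_s * fs_g, ,
                     drop = FALSE]
  # pipeline-convention ground truth: noise-free filtered GRFs normalized
  # over the 20 N threshold intervals (what extract_steps reproduces)
  true_steps_threshold <- lapply(seq_len(nrow(thr_int)), function(k) {
    i <- thr_int[k, "on"]:(thr_int[k, "off"] - 1L)
    list(vert = pmax(0, time_normalize(vert_filt[i])) /
           (subject$mass * .GRAVITY),
         ap = time_normalize(ap_filt[i]) / (subject$mass * .GRAVITY))
  })

  with_seed(child_seed(seed, 999L), {
    if (config$noise_sd_grf > 0)
      grf <- grf + matrix(rnorm(length(grf), 0, config$noise_sd_grf),
                          ncol = 3)
    if (config$noise_sd_pressure > 0) {
      pressure <- pressure +
        matrix(rnorm(length(pressure), 0, config$noise_sd_pressure),
               ncol = ncol(pressure))
      pressure[pressure < 0] <- 0
    }
  })

  # per-step noise-free 101-node ledger curves
  grid <- seq(0, 1, length.out = 101)
  ab <- planted_coefficients()
  W <- lobe_region_weights()
  gain <- subject$idiosyncratic_gain %||% 1
  true_steps <- lapply(seq_len(nrow(plan)), function(k) {
    d <- lobe_curves(grid, unlist(plan$amps[[k]]))
    p <- d %*% t(W)
    list(vert = gain * drop(p %*% ab$A), ap = gain * drop(p %*% ab$B),
         pr = p)
  })

  structure(list(
    pressure = pressure,
    grf = grf,
    fs_pressure = fs_p,
    fs_grf = fs_g,
    condition = list(speed = condition$speed, slope = condition$slope),
    subject = subject,
    foot = foot,
    analysis_start_s = config$analysis_start_s,
    true_lag = as.integer(lag),
    true_step_intervals = thr_int,
    true_stance_times = cbind(on = plan$t_on, off = plan$t_on + plan$dur),
    true_steps = true_steps,
    true_steps_threshold = true_steps_threshold,
    footstrike_used = plan$footstrike[1]
  ), class = "grf_trial")
}

# Half-open [on, off) 1-based intervals where x first exceeds then falls
# below `threshold`; runs shorter than min_len samples are dropped.
threshold_intervals <- function(x, threshold, min_len = 1L) {
  above <- x > threshold
  if (!any(above)) return(matrix(integer(0), 0, 2,
                                 dimnames = list(NULL, c("on", "off"))))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  cbind(on = starts[keep], off = ends[keep] + 1L)
}

#' @export
print.grf_trial <- function(x, ...) {
  cat(sprintf(
    "Synthetic trial: subject %s, %s foot, %.1f m/s at %+.0f deg\n",
    x$subject$subject_id %||% "?", x$foot, x$condition$speed,
    x$condition$slope))
  cat(sprintf("  GRF %d samples @ %g Hz; pressure %d frames @ %g Hz; lag %d\n",
              nrow(x$grf), x$fs_grf, nrow(x$pressure), x$fs_pressure,
              x$true_lag))
  invisible(x)
}

# ---- cohort -----------------------------------------------------------------

make_subjects <- function(config) {
  with_seed(child_seed(config$seed, 1L), {
    n <- config$n_subjects
    ids <- sprintf("S%02d", seq_len(n))
    mass <- pmin(95, pmax(45, rnorm(n, 65.9, 9.3)))
    footstrike <- ifelse(runif(n) < 0.75, "rearfoot", "forefoot")
    switcher <- runif(n) < 0.6
    gains <- config$idiosyncratic_gains
    g <- if (length(gains) == 1L && is.null(names(gains)))
      rep(gains, n) else {
        gg <- rep(1, n); names(gg) <- ids
        gg[names(gains)] <- gains
        gg
      }
    lapply(seq_len(n), function(i) list(
      subject_id = ids[i], mass = mass[i], footstrike = footstrike[i],
      idiosyncratic_gain = unname(g[i]), uphill_switcher = switcher[i]))
  })
}

#' Simulate a full synthetic cohort of raw dual-rate trials
#'
#' Generates one raw trial per (subject, condition, foot) together with a
#' ground-truth ledger: the planted mapping coefficients, per-trial stream
#' lags, stance intervals, and noise-free 101-node GRF curves per step.  The
#' same configuration and seed always produce an identical cohort.
#'
#' @param config A [sim_config()].
#' @return An object of class `grf_cohort`: list with `trials` (list of
#'   [assemble_trial()] outputs), `subjects`, `ledger` and `config`.
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 1, conditions = graded_conditions()[1, ],
#'                   steps_per_trial = 3, seed = 7)
#' cohort <- simulate_cohort(cfg)
#' length(cohort$trials)
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("`config` must be a sim_config object", call. = FALSE)
  subjects <- make_subjects(config)
  grid <- expand.grid(subject = seq_along(subjects),
                      cond = seq_len(nrow(config$conditions)),
                      foot = c("right", "left"),
                      stringsAsFactors = FALSE)
  n_trials <- nrow(grid)
  lags <- config$lag_samples
  if (is.null(lags)) {
    lags <- with_seed(child_seed(config$seed, 2L),
                      sample(-30:30, n_trials, replace = TRUE))
  } else {
    lags <- rep_len(as.integer(lags), n_trials)
  }
  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    cond <- as.list(config$conditions[grid$cond[i], ])
    trials[[i]] <- assemble_trial(
      config, subjects[[grid$subject[i]]], cond, foot = grid$foot[i],
      lag = lags[i], seed = child_seed(config$seed, 100L + i))
  }
  ledger <- list(
    coefficients = planted_coefficients(),
    mapping_mode = config$mapping_mode,
    sat_scale = SAT_SCALE,
    trials = lapply(trials, function(tr) list(
      subject_id = tr$subject$subject_id,
      condition = tr$condition,
      foot = tr$foot,
      true_lag = tr$true_lag,
      true_step_intervals = tr$true_step_intervals,
      true_stance_times = tr$true_stance_times,
      true_steps = tr$true_steps,
      true_steps_threshold = tr$true_steps_threshold))
  )
  structure(list(trials = trials, subjects = subjects, ledger = ledger,
                 config = config),
            class = "grf_cohort")
}

#' @export
print.grf_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d subjects, %d conditions, %d trials (%s mapping)\n",
    length(x$subjects), nrow(x$config$conditions), length(x$trials),
    x$config$mapping_mode))
  invisible(x)
}

# ---- analytic step datasets -------------------------------------------------

#' Simulate time-normalized steps directly on the 101-node phase grid
#'
#' Bypasses the raw dual-rate rendering and produces a [step_dataset()] whose
#' channels are evaluated analytically on the phase grid.  In linear mapping
#' mode the planted coefficients reproduce the GRFs from the region curves
#' *exactly* (up to the subject gain), which makes this the reference input
#' for model-recovery tests; in saturating mode the regions are compressed so
#' no linear model is exact.  Per-step lobe jitter provides step-to-step
#' variability without breaking the mapping.
#'
#' @param config A [sim_config()]; `fs_*`, lags and noise settings are
#'   ignored except `noise_steps` below.
#' @param noise_sd_pr,noise_sd_grf Optional additive Gaussian noise on the
#'   mass-normalized region curves and the BW force curves (default 0:
#'   noise-free construction).
#' @return A [step_dataset()] with attribute `"true_coefficients"`.
#' @export
simulate_steps <- function(config, noise_sd_pr = 0, noise_sd_grf = 0) {
  if (!inherits(config, "sim_config"))
    stop("`config` must be a sim_config object", call. = FALSE)
  subjects <- make_subjects(config)
  grid <- seq(0, 1, length.out = 101)
  ab <- planted_coefficients()
  W <- lobe_region_weights()
  rows <- list(); prs <- list(); verts <- list(); aps <- list()
  idx <- 0L
  for (si in seq_along(subjects)) {
    sub <- subjects[[si]]
    for (ci in seq_len(nrow(config$conditions))) {
      cond <- as.list(config$conditions[ci, ])
      for (foot in c("right", "left")) {
        idx <- idx + 1L
        plan <- trial_plan(config, sub, cond, foot,
                           child_seed(config$seed, 5000L + idx))
        for (k in seq_len(nrow(plan))) {
          d <- lobe_curves(grid, unlist(plan$amps[[k]]))
          p <- d %*% t(W)
          vert <- sub$idiosyncratic_gain * drop(p %*% ab$A)
          ap <- sub$idiosyncratic_gain * drop(p %*% ab$B)
          if (config$mapping_mode == "saturating") p <- saturate_regions(p)
          prs[[length(prs) + 1L]] <- p
          verts[[length(verts) + 1L]] <- vert
          aps[[length(aps) + 1L]] <- ap
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = sub$subject_id, mass = sub$mass,
            speed = cond$speed, slope = cond$slope, foot = foot,
            stance_duration = plan$dur[k], stringsAsFactors = FALSE)
        }
      }
    }
  }
  n <- length(prs)
  pr <- array(0, c(n, 5, 101))
  vert <- matrix(0, n, 101); ap <- matrix(0, n, 101)
  for (i in seq_len(n)) {
    pr[i, , ] <- t(prs[[i]]); vert[i, ] <- verts[[i]]; ap[i, ] <- aps[[i]]
  }
  if (noise_sd_pr > 0 || noise_sd_grf > 0) {
    with_seed(child_seed(config$seed, 77L), {
      if (noise_sd_pr > 0) {
        pr <- pr + array(rnorm(length(pr), 0, noise_sd_pr), dim(pr))
        pr[pr < 0] <- 0
      }
      if (noise_sd_grf > 0) {
        vert <- vert + matrix(rnorm(length(vert), 0, noise_sd_grf), n)
        ap <- ap + matrix(rnorm(length(ap), 0, noise_sd_grf), n)
      }
    })
  }
  ds <- step_dataset(pr, vert, ap, do.call(rbind, rows))
  attr(ds, "true_coefficients") <- ab
  attr(ds, "mapping_mode") <- config$mapping_mode
  ds
}
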