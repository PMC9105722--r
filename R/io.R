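## File formats: HDF5 trial and step-dataset layouts, JSON model bundles,
## CSV pressure import, YAML run configuration.
##
## Conventions: 1-based, half-open [on, off) sample intervals; trial layout
## /subjects/<id>/trials/<key>/ with datasets `pressure` (T_p x 99, kPa) and
## `grf` (T_g x 3, N) and attributes speed_mps, slope_deg, mass_kg, foot,
## fs_pressure, fs_grf.  All writes are atomic (temp file + rename).

trial_key_of <- function(trial) {
  sprintf("%s_%s", condition_key(trial$condition$speed,
                                 trial$condition$slope), trial$foot)
}

with_atomic_file <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

REQUIRED_TRIAL_ATTRS <- c("speed_mps", "slope_deg", "mass_kg", "foot",
                          "fs_pressure", "fs_grf")

write_trial_into <- function(h5, trial) {
  sid <- trial$subject$subject_id
  key <- trial_key_of(trial)
  grp <- sprintf("/subjects/%s/trials/%s", sid, key)
  fid <- rhdf5::H5Fopen(h5)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  for (g in c(sprintf("/subjects/%s", sid),
              sprintf("/subjects/%s/trials", sid), grp)) {
    if (!rhdf5::H5Lexists(fid, g))
      rhdf5::H5Gclose(rhdf5::H5Gcreate(fid, g))
  }
  for (ds in c("pressure", "grf")) {
    rhdf5::h5createDataset(fid, paste0(grp, "/", ds), dim(trial[[ds]]),
                           H5type = "H5T_IEEE_F32LE")
  }
  rhdf5::h5writeDataset(trial$pressure, fid, paste0(grp, "/pressure"))
  rhdf5::h5writeDataset(trial$grf, fid, paste0(grp, "/grf"))
  gid <- rhdf5::H5Gopen(fid, grp)
  on.exit(rhdf5::H5Gclose(gid), add = TRUE, after = FALSE)
  rhdf5::h5writeAttribute(trial$condition$speed, gid, "speed_mps")
  rhdf5::h5writeAttribute(trial$condition$slope, gid, "slope_deg")
  rhdf5::h5writeAttribute(trial$subject$mass, gid, "mass_kg")
  rhdf5::h5writeAttribute(trial$foot, gid, "foot")
  rhdf5::h5writeAttribute(trial$fs_pressure, gid, "fs_pressure")
  rhdf5::h5writeAttribute(trial$fs_grf, gid, "fs_grf")
  rhdf5::h5writeAttribute(trial$analysis_start_s %||% 0, gid,
                          "analysis_start_s")
  invisible(NULL)
}

#' Write a raw trial (or a whole cohort) to the HDF5 trial layout
#'
#' @param x A `grf_trial` or `grf_cohort`.
#' @param path Output `.h5` file.
#' @return `path`, invisibly.
#' @export
write_trial <- function(x, path) {
  trials <- if (inherits(x, "grf_cohort")) x$trials else list(x)
  with_atomic_file(path, function(tmp) {
    rhdf5::h5createFile(tmp)
    rhdf5::h5createGroup(tmp, "/subjects")
    for (tr in trials) write_trial_into(tmp, tr)
    rhdf5::h5closeAll()
  })
}

#' @rdname write_trial
#' @export
write_cohort <- write_trial

#' Read one raw trial from the HDF5 trial layout
#'
#' @param path `.h5` file written by [write_trial()].
#' @param subject_id,trial_key Trial address; defaults to the first trial
#'   in the file.
#' @return A `grf_trial`.
#' @export
read_trial <- function(path, subject_id = NULL, trial_key = NULL) {
  idx <- rhdf5::h5ls(path)
  subs <- idx$name[idx$group == "/subjects" & idx$otype == "H5I_GROUP"]
  if (!length(subs)) stop("no /subjects groups in ", path, call. = FALSE)
  subject_id <- subject_id %||% sort(subs)[1]
  tgrp <- sprintf("/subjects/%s/trials", subject_id)
  keys <- idx$name[idx$group == tgrp]
  if (!length(keys))
    stop("no trials for subject ", subject_id, call. = FALSE)
  trial_key <- trial_key %||% sort(keys)[1]
  grp <- sprintf("%s/%s", tgrp, trial_key)
  in_grp <- idx$name[idx$group == grp]
  for (ds in c("pressure", "grf"))
    if (!ds %in% in_grp)
      stop(sprintf("trial %s is missing dataset `%s`", grp, ds),
           call. = FALSE)
  pressure <- rhdf5::h5read(path, paste0(grp, "/pressure"))
  grf <- rhdf5::h5read(path, paste0(grp, "/grf"))
  fid <- rhdf5::H5Fopen(path)
  gid <- rhdf5::H5Gopen(fid, grp)
  attrs <- list()
  for (a in c(REQUIRED_TRIAL_ATTRS, "analysis_start_s")) {
    if (!rhdf5::H5Aexists(gid, a)) {
      rhdf5::H5Gclose(gid); rhdf5::H5Fclose(fid)
      if (a == "analysis_start_s") { attrs[[a]] <- 0; next }
      stop(sprintf("trial %s is missing required attribute `%s`", grp, a),
           call. = FALSE)
    }
    aid <- rhdf5::H5Aopen(gid, a)
    attrs[[a]] <- as.vector(rhdf5::H5Aread(aid))
    rhdf5::H5Aclose(aid)
  }
  rhdf5::h5closeAll()
  structure(list(
    pressure = pressure, grf = grf,
    fs_pressure = attrs$fs_pressure, fs_grf = attrs$fs_grf,
    condition = list(speed = attrs$speed_mps, slope = attrs$slope_deg),
    subject = list(subject_id = subject_id, mass = attrs$mass_kg),
    foot = attrs$foot, analysis_start_s = attrs$analysis_start_s),
    class = "grf_trial")
}

#' List (subject, trial) addresses in an HDF5 trial file
#' @param path `.h5` file.
#' @return Data frame with `subject_id` and `trial_key`.
#' @export
list_trials <- function(path) {
  idx <- rhdf5::h5ls(path)
  tr <- idx[grepl("^/subjects/[^/]+/trials$", idx$group), ]
  data.frame(subject_id = sub("^/subjects/([^/]+)/trials$", "\\1", tr$group),
             trial_key = tr$name, stringsAsFactors = FALSE)
}

#' Read a whole HDF5 trial file as a list of trials
#' @param path `.h5` file.
#' @return List of `grf_trial` objects.
#' @export
read_cohort <- function(path) {
  addr <- list_trials(path)
  lapply(seq_len(nrow(addr)), function(i)
    read_trial(path, addr$subject_id[i], addr$trial_key[i]))
}

# ---- step datasets ----------------------------------------------------------

#' Write/read a step dataset to/from HDF5
#'
#' Layout: `/steps/pr` (N x 5 x 101), `/steps/grf` (N x 2 x 101, components
#' vertical and A/P) and `/steps/meta/<column>` datasets; the config hash
#' and seed used to produce the dataset can be embedded as root attributes.
#'
#' @param data A [step_dataset()].
#' @param path Output `.h5` file.
#' @param config_hash,seed Optional provenance attributes.
#' @return `path` (write) / a `step_dataset` (read).
#' @export
write_step_dataset <- function(data, path, config_hash = NULL, seed = NULL) {
  stopifnot(inherits(data, "step_dataset"))
  with_atomic_file(path, function(tmp) {
    rhdf5::h5createFile(tmp)
    rhdf5::h5createGroup(tmp, "/steps")
    rhdf5::h5createGroup(tmp, "/steps/meta")
    grf <- array(0, c(n_steps(data), 2, 101))
    grf[, 1, ] <- data$vert
    grf[, 2, ] <- data$ap
    rhdf5::h5write(data$pr, tmp, "/steps/pr")
    rhdf5::h5write(grf, tmp, "/steps/grf")
    for (cn in names(data$meta))
      rhdf5::h5write(data$meta[[cn]], tmp, paste0("/steps/meta/", cn))
    fid <- rhdf5::H5Fopen(tmp)
    if (!is.null(config_hash))
      rhdf5::h5writeAttribute(config_hash, fid, "config_hash")
    if (!is.null(seed)) rhdf5::h5writeAttribute(seed, fid, "seed")
    rhdf5::H5Fclose(fid)
    rhdf5::h5closeAll()
  })
}

#' @rdname write_step_dataset
#' @export
read_step_dataset <- function(path) {
  pr <- rhdf5::h5read(path, "/steps/pr")
  grf <- rhdf5::h5read(path, "/steps/grf")
  meta_cols <- rhdf5::h5ls(path)
  meta_cols <- meta_cols$name[meta_cols$group == "/steps/meta"]
  meta <- as.data.frame(lapply(setNames(meta_cols, meta_cols), function(cn)
    as.vector(rhdf5::h5read(path, paste0("/steps/meta/", cn)))),
    stringsAsFactors = FALSE)
  rhdf5::h5closeAll()
  step_dataset(pr, grf[, 1, ], grf[, 2, ], meta)
}

# ---- model serialization ----------------------------------------------------

#' Serialize a linear GRF model to JSON (and back)
#'
#' @param model A [grf_lm()] fit.
#' @param path JSON file.
#' @return `path` / a `grf_lm`.
#' @export
write_grf_lm <- function(model, path) {
  stopifnot(inherits(model, "grf_lm"))
  obj <- list(type = "grf_lm", scope = model$scope,
              intercept = model$intercept, n_steps = model$n_steps,
              coefficients = lapply(model$coefficients, function(co)
                list(A = unname(co[, "A"]), B = unname(co[, "B"]))))
  with_atomic_file(path, function(tmp)
    jsonlite::write_json(obj, tmp, digits = NA, auto_unbox = TRUE))
}

#' @rdname write_grf_lm
#' @export
read_grf_lm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "grf_lm")) stop("not a grf_lm file", call. = FALSE)
  rn <- c(if (isTRUE(obj$intercept)) "(Intercept)", paste0("PR", 1:5))
  co <- lapply(obj$coefficients, function(ab) {
    m <- cbind(A = ab$A, B = ab$B)
    rownames(m) <- rn
    m
  })
  structure(list(coefficients = co, scope = obj$scope,
                 intercept = obj$intercept, n_steps = obj$n_steps),
            class = "grf_lm")
}

#' Save/load a trained recurrent network
#'
#' Weights go to `<prefix>.rds` (native serialization); a JSON sidecar
#' `<prefix>.json` records the architecture, normalization statistics,
#' seeds and training options for reproducibility.
#'
#' @param net A `grf_rnn`.
#' @param prefix Output path prefix.
#' @return The prefix / a `grf_rnn`.
#' @export
save_grf_rnn <- function(net, prefix) {
  stopifnot(inherits(net, "grf_rnn"))
  with_atomic_file(paste0(prefix, ".rds"), function(tmp)
    saveRDS(net, tmp))
  sidecar <- list(type = "grf_rnn", spec = unclass(net$spec),
                  seed = net$seed,
                  norm_stats = if (!is.null(net$norm_stats))
                    unclass(net$norm_stats),
                  options = if (!is.null(net$options))
                    unclass(net$options),
                  trained = net$trained)
  with_atomic_file(paste0(prefix, ".json"), function(tmp)
    jsonlite::write_json(sidecar, tmp, digits = NA, auto_unbox = TRUE))
  invisible(prefix)
}

#' @rdname save_grf_rnn
#' @export
load_grf_rnn <- function(prefix) readRDS(paste0(prefix, ".rds"))

# ---- CSV import -------------------------------------------------------------

#' Import a per-frame pressure CSV
#'
#' Expected format: a time column (named `time`, seconds) followed by 99
#' sensor columns.  Returns the pressure matrix with the sampling rate
#' inferred from the time column, ready to be placed in a trial.
#'
#' @param path CSV file.
#' @return `T x 99` matrix with attribute `"fs"` (Hz).
#' @export
read_pressure_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df))
    stop("pressure CSV needs a `time` column", call. = FALSE)
  sens <- as.matrix(df[, setdiff(names(df), "time"), drop = FALSE])
  if (ncol(sens) != 99)
    stop(sprintf("expected 99 sensor columns, got %d", ncol(sens)),
         call. = FALSE)
  dt <- diff(df$time)
  structure(unname(sens), fs = 1 / stats::median(dt))
}

# ---- run configuration ------------------------------------------------------

default_run_config <- function() {
  list(
    paths = list(raw = NULL, steps = NULL, out = "."),
    simulate = list(n_subjects = 6, steps_per_trial = 10,
                    mapping_mode = "linear", noise_sd_pressure = 0.5,
                    noise_sd_grf = 5),
    preprocess = list(cutoff = 50, order = 3, threshold_N = 20,
                      min_stance_s = 0.1, min_flight_s = 0.05,
                      n_nodes = 101),
    model = list(kind = "linear_pooled", reduced = TRUE, intercept = FALSE),
    training = list(learning_rate = 1e-3, batch_size = 64, max_epochs = 30,
                    val_fraction = 0.1, patience = 5),
    evaluation = list(alpha = 0.05, n_spm_steps = 18),
    seeds = list(global = 1)
  )
}

#' Read and validate a YAML run configuration
#'
#' Unknown keys (at the top level or within a section) are rejected;
#' omitted keys take their defaults.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return Validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad))
      stop("unknown config section(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    for (sec in names(user)) {
      badk <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
      if (length(badk))
        stop(sprintf("unknown key(s) in `%s`: %s", sec,
                     paste(badk, collapse = ", ")), call. = FALSE)
      cfg[[sec]] <- modifyList(cfg[[sec]], user[[sec]])
    }
  }
  structure(cfg, class = "run_config")
}

#' Short content hash of a configuration (for output provenance)
#' @param cfg A `run_config` or any serializable list.
#' @return Character md5 digest.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
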