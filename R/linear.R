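## Least-squares linear GRF estimators.
##
## Model form, per target component and coefficient scope:
##   GRF(phase) = sum_i coef_i * PR_i(phase)
## with PR_i the mass-normalized region pressures.  All 101 nodes of all
## in-scope steps are pooled as observations; one coefficient set per target
## ("pooled" scope) or one per speed/slope condition ("per_condition").

#' Fit least-squares linear GRF models
#'
#' Regresses the 101-node vertical and anterior-posterior GRF targets (body
#' weights) onto the five mass-normalized pressure-region curves, pooling
#' every node of every in-scope step as an observation.  With
#' `scope = "per_condition"` an independent coefficient pair (A, B) is
#' solved for each speed/slope condition, which lets condition enter the
#' model without being an explicit regressor; with `scope = "pooled"` a
#' single pair covers all conditions.
#'
#' @param data A [step_dataset()].
#' @param scope `"pooled"` or `"per_condition"`.
#' @param intercept Include an intercept term (default `FALSE`: the model is
#'   a pure linear combination of region pressures).
#' @return An object of class `grf_lm` with components `coefficients` (named
#'   list per condition, or `$pooled`, each a 2-column matrix `A`, `B`),
#'   `scope`, `intercept` and the training metadata.
#' @seealso [predict.grf_lm()], [grf_rnn()]
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 2, conditions = graded_conditions()[1:2, ],
#'                   steps_per_trial = 4, seed = 3)
#' fit <- grf_lm(simulate_steps(cfg), scope = "pooled")
#' coef(fit)
grf_lm <- function(data, scope = c("pooled", "per_condition"),
                   intercept = FALSE) {
  scope <- match.arg(scope)
  stopifnot(inherits(data, "step_dataset"))
  groups <- if (scope == "pooled") {
    list(pooled = seq_len(n_steps(data)))
  } else {
    keys <- condition_key(data$meta$speed, data$meta$slope)
    split(seq_len(n_steps(data)), keys)
  }
  min_steps <- 5L
  fits <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    if (length(idx) < min_steps)
      stop(sprintf("condition %s has %d steps; at least %d are required",
                   g, length(idx), min_steps), call. = FALSE)
    X <- design_matrix(data, idx, intercept)
    qx <- qr(X)
    if (qx$rank < ncol(X))
      stop(sprintf("rank-deficient pressure design for condition %s", g),
           call. = FALSE)
    A <- qr.coef(qx, as.vector(t(data$vert[idx, , drop = FALSE])))
    B <- qr.coef(qx, as.vector(t(data$ap[idx, , drop = FALSE])))
    cbind(A = A, B = B)
  })
  names(fits) <- names(groups)
  structure(list(coefficients = fits, scope = scope, intercept = intercept,
                 n_steps = n_steps(data),
                 conditions = unique(data$meta[, c("speed", "slope")])),
            class = "grf_lm")
}

design_matrix <- function(data, idx, intercept) {
  # stack steps x nodes into rows; columns = 5 regions (+ intercept)
  X <- matrix(0, length(idx) * 101, 5)
  for (r in 1:5) X[, r] <- as.vector(t(data$pr[idx, r, ]))
  colnames(X) <- paste0("PR", 1:5)
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  X
}

#' @export
print.grf_lm <- function(x, ...) {
  cat(sprintf("Linear GRF model (%s scope%s), trained on %d steps\n",
              x$scope, if (x$intercept) ", with intercept" else "",
              x$n_steps))
  if (x$scope == "pooled") {
    print(round(t(x$coefficients$pooled), 4))
  } else {
    cat(sprintf("  %d condition coefficient pairs: %s\n",
                length(x$coefficients),
                paste(head(names(x$coefficients), 4), collapse = ", ")))
  }
  invisible(x)
}

#' @export
coef.grf_lm <- function(object, ...) {
  if (object$scope == "pooled") object$coefficients$pooled
  else object$coefficients
}

#' Predict GRF curves from a linear model
#'
#' @param object A fitted [grf_lm()].
#' @param newdata A [step_dataset()].
#' @param ... Unused.
#' @return Array `n x 2 x 101` (components vertical, anterior-posterior, in
#'   body weights).  Deterministic; no clipping is applied.
#' @export
predict.grf_lm <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "step_dataset"))
  n <- n_steps(newdata)
  out <- array(0, c(n, 2, 101),
               dimnames = list(NULL, c("vert", "ap"), NULL))
  keys <- if (object$scope == "pooled") rep("pooled", n)
          else condition_key(newdata$meta$speed, newdata$meta$slope)
  unknown <- setdiff(unique(keys), names(object$coefficients))
  if (length(unknown))
    stop("no coefficients for condition(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (g in unique(keys)) {
    idx <- which(keys == g)
    X <- design_matrix(newdata, idx, object$intercept)
    co <- object$coefficients[[g]]
    yv <- X %*% co[, "A"]
    ya <- X %*% co[, "B"]
    out[idx, 1, ] <- matrix(yv, length(idx), 101, byrow = TRUE)
    out[idx, 2, ] <- matrix(ya, length(idx), 101, byrow = TRUE)
  }
  out
}

#' @export
residuals.grf_lm <- function(object, data, ...) {
  pred <- predict(object, data)
  list(vert = data$vert - pred[, 1, ], ap = data$ap - pred[, 2, ])
}

#' @export
summary.grf_lm <- function(object, data = NULL, ...) {
  out <- list(model = object)
  if (!is.null(data)) out$metrics <- step_metrics(predict(object, data), data)
  class(out) <- "summary.grf_lm"
  out
}

#' @export
print.summary.grf_lm <- function(x, ...) {
  print(x$model)
  if (!is.null(x$metrics)) {
    agg <- stats::aggregate(
      cbind(rmse, r) ~ speed + slope + component, data = x$metrics, mean)
    cat("\nMean per-step metrics by condition:\n")
    print(agg, digits = 3)
  }
  invisible(x)
}

#' @export
plot.grf_lm <- function(x, ...) {
  co <- if (x$scope == "pooled") x$coefficients$pooled else
    Reduce(`+`, x$coefficients) / length(x$coefficients)
  rows <- if (x$intercept) -1L else TRUE
  graphics::barplot(t(co[rows, , drop = FALSE]), beside = TRUE,
                    names.arg = paste0("PR", 1:5),
                    legend.text = c("A (vertical)", "B (A/P)"),
                    ylab = "coefficient (BW per normalized pressure)", ...)
  invisible(x)
}
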