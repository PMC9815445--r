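#' Data-handling transform for MAR estimation
#'
#' The MAR workflow supports four data-handling variants — raw or
#' log-transformed, unsmoothed or smoothed — plus z-scoring.  Transforms are
#' applied in a fixed order: replicate averaging (always; MAR needs one row
#' per time), zero replacement, log, optional smoothing (resampled at the
#' observation times), optional z-scoring.  Everything applied is recorded
#' so predictions can be mapped back to abundance scale.
#'
#' @param data Observed [abundance_data] (or coercible).
#' @param log Apply the natural log (Gompertz interpretation).
#' @param zero_replacement Value substituted for zeros before the log
#'   (default `1e-5`); recorded as lossy.
#' @param zscore Z-score each species column after the other steps.
#' @param smooth_df Per-species spline df for the optional smoothing step,
#'   or `NULL` for no smoothing.
#' @return List with `data` (the transformed [abundance_data]) and `record`
#'   (a `"transform_record"` sufficient to invert the transform, up to the
#'   recorded zero replacement and smoothing).
#' @export
prepare_transform <- function(data, log = FALSE, zero_replacement = 1e-5,
                              zscore = FALSE, smooth_df = NULL) {
  data <- average_replicates(as_abundance_data(data))
  vals <- data$values
  zeros_replaced <- 0L
  if (log) {
    if (any(vals < 0, na.rm = TRUE)) {
      stop("negative abundances: cannot log-transform", call. = FALSE)
    }
    z <- which(vals == 0)
    zeros_replaced <- length(z)
    vals[z] <- zero_replacement
    vals <- base::log(vals)
  }
  out <- abundance_data(data$times, vals, species = data$species)
  if (!is.null(smooth_df)) {
    sm <- fit_spline(out, df = smooth_df)
    ev <- eval_smooth(sm, out$times)
    out <- abundance_data(out$times, ev$values, species = data$species)
  }
  means <- rep(0, n_species(data)); sds <- rep(1, n_species(data))
  if (zscore) {
    means <- colMeans(out$values, na.rm = TRUE)
    sds <- apply(out$values, 2, stats::sd, na.rm = TRUE)
    if (any(sds == 0)) stop("constant species column: cannot z-score", call. = FALSE)
    out <- abundance_data(out$times, scale(out$values, center = means, scale = sds),
                          species = data$species)
  }
  record <- structure(list(log_applied = log,
                           zero_replacement = zero_replacement,
                           zeros_replaced = zeros_replaced,
                           zscore_applied = zscore,
                           means = means, sds = sds,
                           smoothing_df = smooth_df,
                           species = data$species),
                      class = "transform_record")
  list(data = out, record = record)
}

#' @export
print.transform_record <- function(x, ...) {
  cat(sprintf("<transform_record> log: %s, zscore: %s, smoothing df: %s\n",
              x$log_applied, x$zscore_applied,
              if (is.null(x$smoothing_df)) "none" else
                paste(x$smoothing_df, collapse = ", ")))
  invisible(x)
}

## Snap observation times to an integer grid index.  MAR(1) is defined on a
## fixed step; only truly consecutive pairs enter the estimation.
snap_to_grid <- function(times, step = NULL) {
  tt <- sort(unique(times))
  if (is.null(step)) {
    if (length(tt) < 2) stop("need at least 2 distinct times", call. = FALSE)
    step <- min(diff(tt))
  }
  list(idx = as.integer(round((times - tt[1]) / step)),
       t0 = tt[1], step = step)
}

#' Fit a MAR(1) model by conditional least squares
#'
#' Estimates the intercepts `alpha` and transition matrix `beta` by
#' regressing each observed state on the immediately preceding one over all
#' consecutive-pair observations (conditional least squares, the exact
#' Gaussian MLE for a fully observed, equally spaced MAR(1) with no
#' observation error).  Observation times are snapped to an integer grid of
#' the given step; gaps simply contribute no pairs.  The process covariance
#' `delta` is the residual covariance with denominator
#' `pairs - parameters per equation`.
#'
#' @param data [abundance_data] on (a possibly gappy subset of) a regular
#'   time grid, one row per time (average replicates first).
#' @param step Grid step; default the smallest positive spacing in the data.
#' @param diagonal_only Keep only the diagonal of the residual covariance.
#' @return A [mar_params] estimate with attributes `n_pairs`, `std_errors`
#'   (an `n x (n+1)` matrix of CLS coefficient standard errors, intercept
#'   first) and `step`.
#' @export
fit_mar <- function(data, step = NULL, diagonal_only = FALSE) {
  data <- as_abundance_data(data)
  if (!is.null(data$replicate)) {
    stop("average replicates before MAR estimation (see `average_replicates()`)",
         call. = FALSE)
  }
  n <- n_species(data)
  g <- snap_to_grid(data$times, step)
  ord <- order(g$idx)
  idx <- g$idx[ord]
  vals <- data$values[ord, , drop = FALSE]
  complete <- rowSums(is.na(vals)) == 0
  pair_from <- which(diff(idx) == 1 & complete[-length(idx)] & complete[-1])
  m <- length(pair_from)
  if (m < n + 2) {
    stop(sprintf("need at least n + 2 = %d consecutive-pair observations (found %d)",
                 n + 2, m), call. = FALSE)
  }
  Xt <- vals[pair_from, , drop = FALSE]
  Xt1 <- vals[pair_from + 1L, , drop = FALSE]
  design <- cbind(1, Xt)
  fit <- stats::lm.fit(design, Xt1)
  if (fit$rank < n + 1) {
    stop("collinear design (e.g. an exactly constant series): cannot separate intercept and lag terms",
         call. = FALSE)
  }
  coefs <- matrix(fit$coefficients, n + 1, n)   # (n+1) x n, responses in cols
  alpha <- coefs[1, ]
  beta <- t(coefs[-1, , drop = FALSE])          # row = affected species
  resid <- matrix(fit$residuals, m, n)
  dof <- m - (n + 1)
  delta <- crossprod(resid) / dof
  delta <- (delta + t(delta)) / 2
  if (diagonal_only) delta <- diag(diag(delta), n)
  XtX_inv <- chol2inv(chol(crossprod(design)))
  sig2 <- colSums(resid^2) / dof
  se <- sqrt(outer(sig2, diag(XtX_inv)))        # n x (n+1)
  out <- mar_params(alpha, beta, delta, species = data$species)
  attr(out, "n_pairs") <- m
  attr(out, "std_errors") <- se
  attr(out, "step") <- g$step
  out
}

#' Predict from a fitted MAR(1) model
#'
#' `free_run` iterates the noise-free recursion from the first observation
#' across the full (snapped) grid spanned by the data; `one_step` predicts
#' each observed state from the observed preceding state.
#'
#' @param params A [mar_params] object.
#' @param data [abundance_data] on the model scale.
#' @param mode `"free_run"` or `"one_step"`.
#' @param step Grid step (default: smallest spacing, as in [fit_mar()]).
#' @return A [trajectory] on the model scale.
#' @export
predict_mar <- function(params, data, mode = c("free_run", "one_step"),
                        step = NULL) {
  mode <- match.arg(mode)
  data <- as_abundance_data(data)
  n <- n_species(data)
  if (length(params$intercepts) != n) stop("dimension mismatch", call. = FALSE)
  g <- snap_to_grid(data$times, step)
  ord <- order(g$idx)
  idx <- g$idx[ord]
  vals <- data$values[ord, , drop = FALSE]
  if (mode == "free_run") {
    first <- which(rowSums(is.na(vals)) == 0)[1]
    if (is.na(first)) stop("no complete observation to start from", call. = FALSE)
    steps <- max(idx) - idx[first]
    x <- vals[first, ]
    out <- matrix(NA_real_, steps + 1L, n)
    out[1, ] <- x
    for (s in seq_len(steps)) {
      x <- drop(params$intercepts + params$transition %*% x)
      out[s + 1L, ] <- x
    }
    trajectory(g$t0 + g$step * (idx[first] + 0:steps), out,
               species = data$species)
  } else {
    complete <- rowSums(is.na(vals)) == 0
    from <- which(diff(idx) == 1 & complete[-length(idx)])
    if (length(from) == 0) stop("no consecutive pairs to predict", call. = FALSE)
    pred <- t(apply(vals[from, , drop = FALSE], 1, function(x)
      drop(params$intercepts + params$transition %*% x)))
    trajectory(g$t0 + g$step * idx[from + 1L], pred, species = data$species)
  }
}

#' Invert a recorded data transform
#'
#' Maps a model-scale trajectory back to abundance scale: z-scoring is
#' inverted first, then the log is exponentiated.  Smoothing and zero
#' replacement are lossy and are not inverted (they are recorded).
#'
#' @param traj A [trajectory] on the transformed scale.
#' @param record The `"transform_record"` from [prepare_transform()].
#' @return A [trajectory] on abundance scale.
#' @export
back_transform <- function(traj, record) {
  if (!inherits(record, "transform_record")) {
    stop("`record` must be a transform_record", call. = FALSE)
  }
  vals <- traj$values
  if (record$zscore_applied) {
    vals <- sweep(sweep(vals, 2, record$sds, `*`), 2, record$means, `+`)
  }
  if (record$log_applied) vals <- exp(vals)
  trajectory(traj$times, vals, species = traj$species)
}

#' Gaussian prediction intervals for a MAR free run
#'
#' Propagates the process-noise covariance along the free-run mean,
#' `V_{t+1} = beta V_t beta' + delta` with `V_0 = 0`, and returns pointwise
#' Gaussian intervals on the model scale.
#'
#' @param params A [mar_params] object.
#' @param traj The free-run mean [trajectory] (model scale).
#' @param level Coverage probability in (0, 1).
#' @return List of matrices `lower` and `upper`, shaped like `traj$values`.
#' @export
prediction_interval <- function(params, traj, level = 0.95) {
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)", call. = FALSE)
  n <- length(params$intercepts)
  z <- stats::qnorm(1 - (1 - level) / 2)
  V <- matrix(0, n, n)
  half <- matrix(0, nrow(traj$values), n)
  for (s in seq_len(nrow(traj$values) - 1L)) {
    V <- params$transition %*% V %*% t(params$transition) + params$process_covariance
    half[s + 1L, ] <- z * sqrt(pmax(diag(V), 0))
  }
  list(lower = traj$values - half, upper = traj$values + half)
}
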