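#' Fit cubic smoothing splines with stated degrees of freedom
#'
#' Smooths each species of an observed series independently with a cubic
#' smoothing spline of the requested effective degrees of freedom (the
#' "NDF-spline" of the inference workflow).  Replicated rows enter the
#' penalized fit jointly, so replication weights the fit rather than being
#' pre-averaged.  Rows with a missing value for a species are dropped for
#' that species only.
#'
#' @param data An [abundance_data] object (or coercible).
#' @param df Requested effective degrees of freedom; scalar or one value
#'   per species.  Must lie in `[2, number of distinct times]`.
#' @return An object of class `"smoothed_traj"`: per-species spline fits,
#'   requested and achieved df, and the fit interval.
#' @seealso [eval_smooth()], [resample_spline()]
#' @export
fit_spline <- function(data, df) {
  data <- as_abundance_data(data)
  n <- n_species(data)
  df <- rep_len(df, n)
  n_distinct <- length(unique(data$times))
  if (n_distinct < 4) {
    stop("need at least 4 distinct time points for a cubic smoothing spline",
         call. = FALSE)
  }
  if (any(df < 2) || any(df > n_distinct)) {
    stop(sprintf("`df` must lie in [2, %d] (number of distinct times)", n_distinct),
         call. = FALSE)
  }
  fits <- vector("list", n)
  edf <- numeric(n)
  for (i in seq_len(n)) {
    ok <- !is.na(data$values[, i])
    if (length(unique(data$times[ok])) < 4) {
      stop(sprintf("species '%s' has fewer than 4 distinct observed times",
                   data$species[i]), call. = FALSE)
    }
    fits[[i]] <- stats::smooth.spline(data$times[ok], data$values[ok, i],
                                      df = df[i], all.knots = TRUE,
                                      keep.data = FALSE)
    edf[i] <- fits[[i]]$df
  }
  structure(list(fits = fits, df = df, edf = edf,
                 fit_interval = range(data$times),
                 species = data$species),
            class = "smoothed_traj")
}

#' @export
print.smoothed_traj <- function(x, ...) {
  cat(sprintf("<smoothed_traj> %d species, df = [%s], t in [%g, %g]\n",
              length(x$species), paste(signif(x$edf, 4), collapse = ", "),
              x$fit_interval[1], x$fit_interval[2]))
  invisible(x)
}

#' Evaluate a smoothed trajectory and its slopes
#'
#' Returns the smoothed curve values and first derivatives at the requested
#' times.  Requests outside the fit interval are refused: spline slopes
#' outside the data are untrustworthy.
#'
#' @param smoothed A [fit_spline()] result.
#' @param times Times inside the fit interval.
#' @return List with matrices `values` and `slopes` (rows = times,
#'   columns = species).
#' @export
eval_smooth <- function(smoothed, times) {
  iv <- smoothed$fit_interval
  eps <- 1e-8 * max(1, abs(iv))
  if (any(times < iv[1] - eps | times > iv[2] + eps)) {
    stop(sprintf("requested times outside the fit interval [%g, %g]: no extrapolation",
                 iv[1], iv[2]), call. = FALSE)
  }
  n <- length(smoothed$species)
  values <- slopes <- matrix(NA_real_, length(times), n,
                             dimnames = list(NULL, smoothed$species))
  for (i in seq_len(n)) {
    values[, i] <- stats::predict(smoothed$fits[[i]], times)$y
    slopes[, i] <- stats::predict(smoothed$fits[[i]], times, deriv = 1)$y
  }
  list(values = values, slopes = slopes)
}

#' Resample a smoothed trajectory into a slope point set
#'
#' Evaluates the smoothed curves (values and slopes) either at explicit
#' times or at `n` equispaced times across the fit interval.  The result is
#' the [slope_points] input that the algebraic LV inference consumes.
#'
#' @param smoothed A [fit_spline()] result.
#' @param times Explicit times (inside the fit interval), or `NULL`.
#' @param n Number of equispaced times, used when `times` is `NULL`.
#' @return A [slope_points] object.
#' @export
resample_spline <- function(smoothed, times = NULL, n = NULL) {
  if (is.null(times)) {
    if (is.null(n)) stop("supply `times` or `n`", call. = FALSE)
    times <- seq(smoothed$fit_interval[1], smoothed$fit_interval[2],
                 length.out = n)
  }
  ev <- eval_smooth(smoothed, times)
  slope_points(times, ev$values, ev$slopes)
}

#' Average replicated observations per time point
#'
#' Collapses an observed series to one row per distinct time, each species
#' value being the arithmetic mean over the replicates observed at that
#' time (missing entries excluded).  MAR estimation requires this; the
#' spline fit does not.
#'
#' @param data An [abundance_data] object (or coercible).
#' @return An [abundance_data] without replicate labels.
#' @export
average_replicates <- function(data) {
  data <- as_abundance_data(data)
  if (is.null(data$replicate)) return(data)
  tt <- sort(unique(data$times))
  vals <- matrix(NA_real_, length(tt), n_species(data))
  for (k in seq_along(tt)) {
    rows <- data$values[data$times == tt[k], , drop = FALSE]
    vals[k, ] <- colMeans(rows, na.rm = TRUE)
  }
  vals[is.nan(vals)] <- NA_real_
  abundance_data(tt, vals, species = data$species)
}
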