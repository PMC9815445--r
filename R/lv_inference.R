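#' Slope point set for algebraic LV inference
#'
#' Abundance/slope pairs at a set of times, the algebraic form of the LV
#' estimation problem: substituting estimated slopes for the derivatives
#' leaves the parameters as the only unknowns.
#'
#' @param times Numeric vector.
#' @param values Matrix of abundances (rows = points, cols = species).
#' @param slopes Matrix of slope estimates, same shape as `values`.
#' @return An object of class `"slope_points"`.
#' @export
slope_points <- function(times, values, slopes) {
  values <- as.matrix(values); slopes <- as.matrix(slopes)
  if (!all(dim(values) == dim(slopes))) {
    stop("`values` and `slopes` must have the same shape", call. = FALSE)
  }
  if (length(times) != nrow(values)) {
    stop("`times` must have one entry per row", call. = FALSE)
  }
  species <- colnames(values)
  if (is.null(species)) species <- paste0("X", seq_len(ncol(values)))
  colnames(values) <- colnames(slopes) <- species
  structure(list(times = as.numeric(times), values = values, slopes = slopes,
                 species = species),
            class = "slope_points")
}

#' @export
print.slope_points <- function(x, ...) {
  cat(sprintf("<slope_points> %d points x %d species\n",
              length(x$times), length(x$species)))
  invisible(x)
}

## Exact slope points of a known LV system along a trajectory (oracle input
## for noise-free recovery checks): values from the trajectory, slopes from
## the model right-hand side.
#' Exact slope points of a known LV system
#'
#' Evaluates a simulated trajectory at selected times and attaches the exact
#' model slopes `X (a + B X)`.  On such noise-free input both ALVI variants
#' recover the generating parameters exactly (up to conditioning).
#'
#' @param params The generating [lv_params].
#' @param traj A [trajectory] of that system.
#' @param times Subset of `traj$times` to use.
#' @return A [slope_points] object.
#' @export
exact_slope_points <- function(params, traj, times) {
  idx <- match_times(times, traj$times)
  vals <- traj$values[idx, , drop = FALSE]
  slope_points(traj$times[idx], vals, lv_slopes(params, vals))
}

#' Build the per-species linear system of algebraic LV inference
#'
#' For species `i`, each point contributes the equation
#' `s_i/X_i = a_i + sum_j b_ij X_j`: response `s_i(t)/X_i(t)`, design row
#' `[1, X_1(t), ..., X_n(t)]`, unknowns `[a_i, b_i1, ..., b_in]`.  Each
#' species' system is independent of the others'.
#'
#' @param points A [slope_points] object with strictly positive abundances.
#' @param species_index Which species' equation to build.
#' @return List with `design` (points x (n+1) matrix) and `response`.
#' @export
build_regression_system <- function(points, species_index) {
  X <- points$values
  bad <- which(X[, species_index] <= 0)
  if (length(bad) > 0) {
    stop(sprintf("non-positive abundance for species '%s' at point %d (t = %g): cannot divide the slope",
                 points$species[species_index], bad[1], points$times[bad[1]]),
         call. = FALSE)
  }
  design <- cbind(1, X)
  colnames(design) <- c("(Intercept)", points$species)
  list(design = design,
       response = points$slopes[, species_index] / X[, species_index])
}

#' Algebraic LV inference by linear regression (ALVI-LR)
#'
#' Ordinary least squares on the per-species algebraic system over all
#' supplied points.
#'
#' @param points A [slope_points] object with at least `n + 1` points.
#' @return An [lv_params] estimate.
#' @export
alvi_lr <- function(points) {
  n <- length(points$species)
  if (nrow(points$values) < n + 1) {
    stop(sprintf("need at least %d points for %d species", n + 1, n), call. = FALSE)
  }
  a <- numeric(n); B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    sys <- build_regression_system(points, i)
    fit <- stats::lm.fit(sys$design, sys$response)
    if (fit$rank < ncol(sys$design)) {
      stop(sprintf("rank-deficient design for species '%s': supply more or better-spread points",
                   points$species[i]), call. = FALSE)
    }
    a[i] <- fit$coefficients[1]
    B[i, ] <- fit$coefficients[-1]
  }
  lv_params(a, B, species = points$species)
}

#' Algebraic LV inference by matrix inversion (ALVI-MI)
#'
#' Exact solve of the square `(n+1) x (n+1)` algebraic system per species on
#' exactly `n + 1` points.  Near-singular systems — typically from
#' insufficient or almost linearly dependent points — are refused with the
#' condition number reported.
#'
#' @param points A [slope_points] with exactly `n + 1` points.
#' @param cond_threshold Condition-number bound above which the system is
#'   treated as singular (default 1e10).
#' @return An [lv_params] estimate with attribute `condition_number`.
#' @export
alvi_mi <- function(points, cond_threshold = 1e10) {
  n <- length(points$species)
  if (nrow(points$values) != n + 1) {
    stop(sprintf("ALVI-MI needs exactly n + 1 = %d points (got %d)",
                 n + 1, nrow(points$values)), call. = FALSE)
  }
  design <- cbind(1, points$values)
  kap <- kappa(design, exact = TRUE)
  if (!is.finite(kap) || kap > cond_threshold) {
    stop(sprintf("near-singular ALVI-MI system (condition number %.3g): insufficient datapoints or almost-linear dependence",
                 kap), call. = FALSE)
  }
  a <- numeric(n); B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    sys <- build_regression_system(points, i)
    coef <- solve(sys$design, sys$response)
    a[i] <- coef[1]
    B[i, ] <- coef[-1]
  }
  out <- lv_params(a, B, species = points$species)
  attr(out, "condition_number") <- kap
  out
}

## ---- trajectory SSE objective --------------------------------------------

## Reference series for scoring a fit: observed data, smoothed trend, or
## noise-free truth.  Returns an abundance_data to score against.
resolve_reference <- function(reference = c("data", "smooth", "truth"),
                              data = NULL, smoothed = NULL, truth = NULL) {
  reference <- match.arg(reference)
  switch(reference,
    data = {
      if (is.null(data)) stop("reference 'data' needs `data`", call. = FALSE)
      as_abundance_data(data)
    },
    smooth = {
      if (is.null(smoothed)) stop("reference 'smooth' needs `smoothed`", call. = FALSE)
      if (is.null(data)) stop("reference 'smooth' needs `data` for the times", call. = FALSE)
      tt <- sort(unique(as_abundance_data(data)$times))
      ev <- eval_smooth(smoothed, tt)
      abundance_data(tt, ev$values, species = smoothed$species)
    },
    truth = {
      if (is.null(truth)) stop("reference 'truth' needs `truth`", call. = FALSE)
      as_abundance_data(truth)
    })
}

## SSE of the LV trajectory implied by `params`, integrated over the full
## observation window from the given starting state, against a reference.
lv_trajectory_sse <- function(params, x0, ref, overflow = 1e12) {
  tt <- sort(unique(ref$times))
  grid <- list(start_time = tt[1], step = NA, n_steps = NA)
  pred <- tryCatch(
    simulate_lv_ode_at(params, x0, tt, overflow = overflow),
    error = function(e) e)
  if (inherits(pred, "error")) {
    return(list(sse = Inf, pred = NULL, reason = conditionMessage(pred)))
  }
  s <- sse(pred, ref)
  list(sse = s$total, pred = pred, reason = NULL)
}

## ODE solution at an arbitrary increasing set of times.
simulate_lv_ode_at <- function(params, x0, times, overflow = 1e12,
                               rtol = 1e-8, atol = 1e-8) {
  rhs <- function(t, x, p) list(x * (p$a + drop(p$B %*% x)))
  ## capture.output also swallows the solver's Fortran-level step-size
  ## complaints for diverging candidate parameter sets
  invisible(utils::capture.output(
    out <- suppressWarnings(
      deSolve::ode(y = as.numeric(x0), times = times, func = rhs,
                   parms = list(a = params$growth_rates, B = params$interactions),
                   rtol = rtol, atol = atol))))
  vals <- unname(as.matrix(out)[, -1, drop = FALSE])
  if (nrow(out) < length(times) || any(!is.finite(vals)) || any(abs(vals) > overflow)) {
    stop("LV integration diverged during scoring", call. = FALSE)
  }
  trajectory(times, vals, species = params$species)
}

#' Fit result
#'
#' Bundles a fitted model with its predicted trajectory, SSE decomposition
#' and the settings needed to reproduce the fit.
#'
#' @param method Method label (e.g. `"alvi-mi"`).
#' @param params Fitted [lv_params] or [mar_params].
#' @param predicted Predicted [trajectory] (or `NULL` for failed fits).
#' @param sse_per_species Named numeric vector.
#' @param settings List of settings (df, sample times, seed, transforms ...).
#' @return An object of class `"fit_result"`.
#' @export
fit_result <- function(method, params, predicted, sse_per_species,
                       settings = list()) {
  structure(list(method = method, params = params, predicted = predicted,
                 sse_per_species = sse_per_species,
                 sse_total = sum(sse_per_species),
                 settings = settings),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s, total SSE %.6g\n", x$method, x$sse_total))
  invisible(x)
}

#' Subsample search over ALVI-MI point subsets
#'
#' Draws `(n+1)`-point subsets from a pool of resampled spline points, runs
#' ALVI-MI on each, integrates the implied LV system over the observation
#' window from the first (smoothed) observation, and ranks candidates by
#' trajectory SSE against the chosen reference.  Singular or diverging
#' candidates get infinite SSE and are retained with their failure reason.
#' Exhaustive enumeration is capped; above the cap a seeded Monte-Carlo
#' search is forced.
#'
#' @param smoothed A [fit_spline()] result.
#' @param data The observed [abundance_data] the fit window comes from.
#' @param strategy `"exhaustive"` or `"monte_carlo"`.
#' @param n_iter Number of Monte-Carlo draws.
#' @param seed Integer seed (required for Monte-Carlo).
#' @param reference Score against raw `"data"`, the `"smooth"` trend, or
#'   noise-free `"truth"`.
#' @param truth Noise-free [trajectory], required when
#'   `reference = "truth"`.
#' @param pool A [slope_points] candidate pool, or `NULL` to resample
#'   `pool_n` equispaced points from the spline.
#' @param pool_n Pool size when `pool` is `NULL` (default 50).
#' @param max_exhaustive Subset-count cap above which Monte-Carlo is forced
#'   (default 20000).
#' @return An object of class `"fit_ensemble"`: list with `results` (a
#'   data.frame of candidate SSEs and reasons, sorted) and `fits` (the
#'   [fit_result] objects in the same order).
#' @export
subsample_search <- function(smoothed, data,
                             strategy = c("monte_carlo", "exhaustive"),
                             n_iter = 200, seed = NULL,
                             reference = c("data", "smooth", "truth"),
                             truth = NULL, pool = NULL, pool_n = 50,
                             max_exhaustive = 20000) {
  strategy <- match.arg(strategy)
  reference <- match.arg(reference)
  data <- as_abundance_data(data)
  if (is.null(pool)) pool <- resample_spline(smoothed, n = pool_n)
  ## drop pool points where any smoothed abundance is non-positive: the
  ## algebraic transformation divides by X_i
  ok <- rowSums(pool$values <= 0) == 0
  pool <- slope_points(pool$times[ok], pool$values[ok, , drop = FALSE],
                       pool$slopes[ok, , drop = FALSE])
  m <- length(pool$times)
  n <- length(pool$species)
  k <- n + 1
  if (m < k) stop("candidate pool too small", call. = FALSE)
  ref <- resolve_reference(reference, data = data, smoothed = smoothed,
                           truth = truth)
  ## the trajectory is integrated from the first smoothed observation, so
  ## scoring starts where the fit interval does
  t0 <- max(min(ref$times), smoothed$fit_interval[1])
  ref <- restrict_data(ref, t0)
  x0 <- eval_smooth(smoothed, t0)$values[1, ]

  if (strategy == "exhaustive" && choose(m, k) > max_exhaustive) {
    strategy <- "monte_carlo"
  }
  if (strategy == "exhaustive") {
    subsets <- utils::combn(m, k, simplify = FALSE)
  } else {
    if (is.null(seed)) stop("`seed` is required for the Monte-Carlo search",
                            call. = FALSE)
    set.seed(seed)
    subsets <- replicate(n_iter, sort(sample.int(m, k)), simplify = FALSE)
  }

  fits <- vector("list", length(subsets))
  sse_v <- numeric(length(subsets))
  reason <- character(length(subsets))
  for (j in seq_along(subsets)) {
    idx <- subsets[[j]]
    sub <- slope_points(pool$times[idx], pool$values[idx, , drop = FALSE],
                        pool$slopes[idx, , drop = FALSE])
    est <- tryCatch(alvi_mi(sub), error = function(e) e)
    if (inherits(est, "error")) {
      sse_v[j] <- Inf; reason[j] <- conditionMessage(est)
      fits[[j]] <- fit_result("alvi-mi", NULL, NULL, c(total = Inf),
                              settings = list(subset_times = sub$times))
      next
    }
    sc <- lv_trajectory_sse(est, x0, ref)
    sse_v[j] <- sc$sse
    reason[j] <- if (is.null(sc$reason)) "" else sc$reason
    per <- if (is.null(sc$pred)) c(total = Inf) else sse(sc$pred, ref)$per_species
    fits[[j]] <- fit_result("alvi-mi", est, sc$pred, per,
                            settings = list(subset_times = sub$times,
                                            reference = reference, seed = seed))
  }
  ord <- order(sse_v)
  res <- data.frame(rank = seq_along(ord), sse = sse_v[ord],
                    reason = reason[ord],
                    subset = vapply(subsets[ord], function(i)
                      paste(signif(pool$times[i], 6), collapse = ","), ""),
                    stringsAsFactors = FALSE)
  structure(list(results = res, fits = fits[ord], reference = reference),
            class = "fit_ensemble")
}

#' @export
print.fit_ensemble <- function(x, ...) {
  cat(sprintf("<fit_ensemble> %d candidates, best SSE %.6g (reference: %s)\n",
              nrow(x$results), x$results$sse[1], x$reference))
  invisible(x)
}

#' Gradient-based refinement of LV parameters
#'
#' Local minimization of the trajectory SSE starting from an algebraic
#' estimate, using numerically estimated gradients with a quasi-Newton line
#' search (BFGS).  The returned parameters never score worse than the
#' start: if the optimizer fails to improve, the start is returned.
#'
#' @param start Starting [lv_params] (e.g. an ALVI solution).
#' @param data Observed [abundance_data].
#' @param reference,smoothed,truth As in [subsample_search()].
#' @param x0 Starting state for trajectory scoring; defaults to the first
#'   reference observation.
#' @param maxit Optimizer iteration cap.
#' @return A refined [lv_params] with attribute `sse` (final objective).
#' @export
refine_gradient <- function(start, data, reference = c("data", "smooth", "truth"),
                            smoothed = NULL, truth = NULL, x0 = NULL,
                            maxit = 200) {
  reference <- match.arg(reference)
  ref <- resolve_reference(reference, data = data, smoothed = smoothed,
                           truth = truth)
  if (is.null(x0)) {
    first <- which(ref$times == min(ref$times))[1]
    x0 <- ref$values[first, ]
    if (any(is.na(x0))) stop("first reference observation incomplete; supply `x0`",
                             call. = FALSE)
  }
  n <- length(start$species)
  pack <- function(p) c(p$growth_rates, as.vector(p$interactions))
  unpack <- function(v) lv_params(v[seq_len(n)],
                                  matrix(v[-seq_len(n)], n, n),
                                  species = start$species)
  obj <- function(v) {
    sc <- lv_trajectory_sse(unpack(v), x0, ref)
    if (!is.finite(sc$sse)) 1e300 else sc$sse
  }
  f0 <- obj(pack(start))
  if (f0 >= 1e300) stop("objective SSE is not finite at the starting parameters",
                        call. = FALSE)
  opt <- stats::optim(pack(start), obj, method = "BFGS",
                      control = list(maxit = maxit))
  if (opt$value <= f0) {
    out <- unpack(opt$par)
    attr(out, "sse") <- opt$value
  } else {
    out <- start
    attr(out, "sse") <- f0
  }
  out
}
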