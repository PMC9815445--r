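#' Simulate the Lotka-Volterra ODE system
#'
#' Integrates the continuous gLV equations with an adaptive solver
#' ([deSolve::ode()], `lsoda`) and returns the solution on the requested
#' grid.  Divergence is reported, not silently returned: if any state
#' exceeds the overflow bound or the integrator fails, an error of class
#' `"lvmar_blowup"` is thrown carrying the last time at which the state was
#' still valid (`condition$last_valid_time`).
#'
#' @param params An [lv_params] object.
#' @param x0 Non-negative initial state, one entry per species.
#' @param grid A [sim_grid] giving the output times.
#' @param overflow Absolute value beyond which the trajectory counts as
#'   diverged (default 1e12).
#' @param rtol,atol Integrator tolerances.
#' @return A [trajectory].
#' @export
simulate_lv_ode <- function(params, x0, grid, overflow = 1e12,
                            rtol = 1e-8, atol = 1e-8) {
  n <- length(params$species)
  if (length(x0) != n) stop("`x0` length must match species count", call. = FALSE)
  if (any(x0 < 0)) stop("`x0` must be non-negative", call. = FALSE)
  times <- grid_times(grid)
  rhs <- function(t, x, p) list(x * (p$a + drop(p$B %*% x)))
  invisible(utils::capture.output(
    out <- suppressWarnings(
      deSolve::ode(y = as.numeric(x0), times = times, func = rhs,
                   parms = list(a = params$growth_rates, B = params$interactions),
                   rtol = rtol, atol = atol))))
  vals <- unname(as.matrix(out)[, -1, drop = FALSE])
  bad <- !is.finite(vals) | abs(vals) > overflow
  if (nrow(out) < length(times) || any(bad)) {
    last_ok <- if (any(bad)) {
      first_bad <- min(which(rowSums(bad) > 0))
      if (first_bad > 1) out[first_bad - 1, 1] else grid$start_time
    } else {
      out[nrow(out), 1]
    }
    stop(structure(class = c("lvmar_blowup", "error", "condition"),
                   list(message = sprintf(
                          "LV integration diverged (|state| > %g or solver failure); last valid time %g",
                          overflow, last_ok),
                        call = sys.call(-1), last_valid_time = last_ok)))
  }
  trajectory(times, vals, species = params$species)
}

#' Draw multiplicative gamma process-noise factors
#'
#' i.i.d. draws from gamma(shape `k`, scale `1/(k - 1)`), the mode-1
#' parameterization used for process noise.  All draws are strictly
#' positive.
#'
#' @param shape Gamma shape `k` (> 1).
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return Numeric vector of positive factors.
#' @export
draw_process_noise <- function(shape, n, seed = NULL) {
  if (any(shape <= 1)) stop("gamma shape must be > 1", call. = FALSE)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  stats::rgamma(n, shape = shape, scale = 1 / (shape - 1))
}

#' Empirical mode via histogram binning
#'
#' Midpoint of the most populated bin of a fixed-width histogram whose bin
#' centres sit at integer multiples of the width (so round values such as 1
#' fall mid-bin, not on an edge); used to check that the process-noise
#' factor has its empirical mode at 1.
#'
#' @param x Numeric sample.
#' @param bin_width Histogram bin width.
#' @return List with `mode` (modal bin midpoint) and `bin` (its endpoints).
#' @export
empirical_mode <- function(x, bin_width = 0.005) {
  breaks <- seq((floor(min(x) / bin_width) - 0.5) * bin_width,
                max(x) + 1.5 * bin_width, by = bin_width)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  i <- which.max(h$counts)
  list(mode = h$mids[i], bin = c(h$breaks[i], h$breaks[i + 1]))
}

#' Simulate the Euler-discretized Lotka-Volterra system with process noise
#'
#' Iterates
#' \deqn{X_{t+h} = [X_t + h X_t (a + B X_t)] \cdot g_t,}
#' where `g_t` is a per-species mode-1 gamma factor when noise is enabled
#' and 1 otherwise, so the noise-free iteration is exactly Euler's method.
#' By default the factor multiplies the whole updated state, so
#' perturbations accumulate step over step and remain visible near steady
#' state; `noise_on = "increment"` multiplies only the Euler increment
#' instead.
#'
#' If the deterministic update overshoots below zero the value is clipped at
#' 0 and the trajectory is flagged (`attr(, "clipped")`), so that high-noise
#' runs can complete; flagged runs should be excluded from recovery
#' statistics.  A non-finite state aborts with the offending step index.
#'
#' @param params An [lv_params] object.
#' @param x0 Initial state; strictly positive when noise is enabled.
#' @param grid A [sim_grid].
#' @param noise A [noise_spec]; default disabled.
#' @param seed Integer seed, required when noise is enabled.
#' @param noise_on Where the gamma factor applies: the whole updated
#'   `"state"` (default) or the Euler `"increment"` only.
#' @return A [trajectory] with attributes `clipped` (logical) and
#'   `clipped_steps` (integer vector of step indices clipped at zero).
#' @export
simulate_lv_discrete <- function(params, x0, grid,
                                 noise = noise_spec(enabled = FALSE),
                                 seed = NULL,
                                 noise_on = c("state", "increment")) {
  noise_on <- match.arg(noise_on)
  n <- length(params$species)
  if (length(x0) != n) stop("`x0` length must match species count", call. = FALSE)
  if (noise$enabled) {
    if (any(x0 <= 0)) stop("`x0` must be strictly positive when noise is enabled",
                           call. = FALSE)
    if (is.null(seed)) stop("`seed` is required when noise is enabled", call. = FALSE)
    set.seed(seed)
    shape <- rep_len(noise$shape, n)
  }
  a <- params$growth_rates; B <- params$interactions; h <- grid$step
  vals <- matrix(NA_real_, grid$n_steps + 1L, n)
  vals[1, ] <- as.numeric(x0)
  clipped_steps <- integer(0)
  x <- as.numeric(x0)
  for (s in seq_len(grid$n_steps)) {
    inc <- h * x * (a + drop(B %*% x))
    if (noise$enabled) {
      g <- stats::rgamma(n, shape = shape, scale = 1 / (shape - 1))
    } else {
      g <- 1
    }
    x_new <- if (noise_on == "state") (x + inc) * g else x + inc * g
    if (any(!is.finite(x_new))) {
      stop(sprintf("non-finite state at step %d of the discrete LV simulation", s),
           call. = FALSE)
    }
    if (any(x + inc < 0)) {   # deterministic Euler overshoot below zero
      clipped_steps <- c(clipped_steps, s)
      x_new <- pmax(x_new, 0)
    }
    x <- x_new
    vals[s + 1L, ] <- x
  }
  out <- trajectory(grid_times(grid), vals, species = params$species)
  attr(out, "clipped") <- length(clipped_steps) > 0
  attr(out, "clipped_steps") <- clipped_steps
  out
}

#' Simulate a MAR(1) model
#'
#' Iterates `x_{t+1} = alpha + beta x_t + w_t` with
#' `w_t ~ MVN(0, delta)` (`w_t = 0` when `deterministic = TRUE`).  Values
#' are on the model scale; under the Gompertz interpretation that is log
#' abundance, and exponentiation is the caller's responsibility.
#'
#' @param params A [mar_params] object.
#' @param x0 Initial state (model scale).
#' @param n_steps Number of recursion steps; the result has `n_steps + 1`
#'   rows at times `0:n_steps` (times `start_time + 0:n_steps * step` if a
#'   grid is given).
#' @param seed Integer seed; required unless `deterministic`.
#' @param deterministic Suppress the noise term.
#' @param start_time,step Time labelling of the output grid.
#' @return A [trajectory].
#' @export
simulate_mar <- function(params, x0, n_steps, seed = NULL,
                         deterministic = FALSE, start_time = 0, step = 1) {
  n <- length(params$intercepts)
  if (length(x0) != n) stop("`x0` length must match species count", call. = FALSE)
  if (!deterministic) {
    if (is.null(seed)) stop("`seed` is required for a stochastic MAR simulation",
                            call. = FALSE)
    set.seed(seed)
    w <- MASS::mvrnorm(n_steps, mu = rep(0, n), Sigma = params$process_covariance)
    w <- matrix(w, nrow = n_steps)
  }
  vals <- matrix(NA_real_, n_steps + 1L, n)
  vals[1, ] <- as.numeric(x0)
  x <- as.numeric(x0)
  for (s in seq_len(n_steps)) {
    x <- drop(params$intercepts + params$transition %*% x)
    if (!deterministic) x <- x + w[s, ]
    vals[s + 1L, ] <- x
  }
  trajectory(start_time + step * (0:n_steps), vals, species = params$species)
}

## Exact gLV right-hand side: slopes dX/dt at given abundances
## (rows = states); slope_i = x_i (a_i + sum_j b_ij x_j).
lv_slopes <- function(params, values) {
  values <- as.matrix(values)
  a_rows <- matrix(params$growth_rates, nrow(values), ncol(values),
                   byrow = TRUE)
  values * (a_rows + values %*% t(params$interactions))
}
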