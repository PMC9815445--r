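#' Lotka-Volterra model parameters
#'
#' Parameterizes the generalized Lotka-Volterra (gLV) system
#' \deqn{dX_i/dt = X_i (a_i + \sum_j b_{ij} X_j),}
#' with per-time growth-rate constants `a` and the square interaction matrix
#' `B`.  Row `i`, column `j` of `B` is the effect of species `j` on species
#' `i`; the diagonal holds intraspecific (crowding) terms.
#'
#' @param growth_rates Numeric vector of growth rates `a_i`.
#' @param interactions Square numeric matrix `b_ij`, dimension matching
#'   `growth_rates`.
#' @param species Optional species labels.
#' @return An object of class `"lv_params"`.
#' @export
lv_params <- function(growth_rates, interactions, species = NULL) {
  a <- as.numeric(growth_rates)
  B <- as.matrix(interactions)
  if (nrow(B) != ncol(B)) stop("interaction matrix must be square", call. = FALSE)
  if (nrow(B) != length(a)) {
    stop("interaction matrix dimension must equal length of growth rates",
         call. = FALSE)
  }
  if (!all(is.finite(a)) || !all(is.finite(B))) {
    stop("all LV parameters must be finite", call. = FALSE)
  }
  if (is.null(species)) species <- paste0("X", seq_along(a))
  names(a) <- species
  dimnames(B) <- list(species, species)
  structure(list(growth_rates = a, interactions = B, species = species),
            class = "lv_params")
}

#' @export
print.lv_params <- function(x, ...) {
  cat(sprintf("<lv_params> %d species\n", length(x$species)))
  cat("growth rates:\n"); print(x$growth_rates)
  cat("interactions (row = affected, col = affecting):\n")
  print(x$interactions)
  invisible(x)
}

#' MAR(1) model parameters
#'
#' Parameterizes the multivariate autoregressive model of order one,
#' \deqn{x_{t+1} = \alpha + \beta x_t + w_t, \quad w_t \sim MVN(0, \delta).}
#' Under the Gompertz (multispecies competition) interpretation the state is
#' a vector of log abundances; the model itself is agnostic and works on
#' whatever scale the caller supplies.  No stationarity is imposed: the
#' spectral radius of `beta` may exceed one.
#'
#' @param intercepts Numeric vector `alpha`.
#' @param transition Square matrix `beta` (row = affected, col = affecting).
#' @param process_covariance Symmetric positive semi-definite matrix `delta`;
#'   defaults to the zero matrix (a noise-free recursion).
#' @param species Optional species labels.
#' @param tol Eigenvalue tolerance used when checking that
#'   `process_covariance` is positive semi-definite.
#' @return An object of class `"mar_params"`.
#' @export
mar_params <- function(intercepts, transition, process_covariance = NULL,
                       species = NULL, tol = 1e-8) {
  alpha <- as.numeric(intercepts)
  beta <- as.matrix(transition)
  n <- length(alpha)
  if (nrow(beta) != ncol(beta) || nrow(beta) != n) {
    stop("transition matrix must be square with dimension length(intercepts)",
         call. = FALSE)
  }
  if (is.null(process_covariance)) process_covariance <- matrix(0, n, n)
  delta <- as.matrix(process_covariance)
  if (!all(dim(delta) == n)) {
    stop("process covariance dimension mismatch", call. = FALSE)
  }
  if (max(abs(delta - t(delta))) > tol) {
    stop("process covariance must be symmetric", call. = FALSE)
  }
  ev <- eigen(delta, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -tol * max(1, abs(ev[1])))) {
    stop("process covariance must be positive semi-definite", call. = FALSE)
  }
  if (is.null(species)) species <- paste0("X", seq_len(n))
  names(alpha) <- species
  dimnames(beta) <- list(species, species)
  dimnames(delta) <- list(species, species)
  structure(list(intercepts = alpha, transition = beta,
                 process_covariance = delta, species = species),
            class = "mar_params")
}

#' @export
print.mar_params <- function(x, ...) {
  cat(sprintf("<mar_params> %d species\n", length(x$species)))
  cat("intercepts:\n"); print(x$intercepts)
  cat("transition (row = affected, col = affecting):\n"); print(x$transition)
  cat("process covariance:\n"); print(x$process_covariance)
  invisible(x)
}

#' Regular simulation grid
#'
#' @param start_time First time point.
#' @param step Step size `h` (> 0).
#' @param n_steps Number of steps taken; the grid holds `n_steps + 1` times.
#' @return An object of class `"sim_grid"`.
#' @export
sim_grid <- function(start_time = 0, step, n_steps) {
  if (!is.numeric(step) || step <= 0) stop("`step` must be > 0", call. = FALSE)
  if (n_steps < 1) stop("`n_steps` must be >= 1", call. = FALSE)
  structure(list(start_time = start_time, step = step,
                 n_steps = as.integer(n_steps)),
            class = "sim_grid")
}

#' Grid over a time span
#'
#' Convenience constructor for the benchmark default of an `n`-point series
#' over `[t0, t1]` (step `= (t1 - t0)/(n - 1)`).
#'
#' @param t0,t1 Span endpoints.
#' @param n Number of grid points (default 100).
#' @export
span_grid <- function(t0, t1, n = 100) {
  sim_grid(start_time = t0, step = (t1 - t0) / (n - 1), n_steps = n - 1)
}

#' @export
print.sim_grid <- function(x, ...) {
  cat(sprintf("<sim_grid> t0 = %g, h = %g, %d steps (%d points)\n",
              x$start_time, x$step, x$n_steps, x$n_steps + 1L))
  invisible(x)
}

grid_times <- function(grid) grid$start_time + grid$step * (0:grid$n_steps)

#' Multiplicative gamma process-noise specification
#'
#' The per-species, per-step noise factor is drawn from a gamma distribution
#' with shape `k` and scale `1/(k - 1)`, so that its mode is exactly 1.  The
#' shape must exceed 1 for the scale to be defined.  The default
#' `shape = 10000` gives a factor with standard deviation
#' `sqrt(k)/(k - 1)` of about 0.01.
#'
#' @param shape Gamma shape `k` (> 1); scalar or one value per species.
#' @param enabled If `FALSE` the factor is identically 1.
#' @return An object of class `"noise_spec"`.
#' @seealso [draw_process_noise()], [gamma_shape_for_sd()]
#' @export
noise_spec <- function(shape = 10000, enabled = TRUE) {
  if (enabled && any(shape <= 1)) {
    stop("gamma shape must be > 1 (scale 1/(k - 1) undefined otherwise)",
         call. = FALSE)
  }
  structure(list(shape = shape, enabled = isTRUE(enabled)),
            class = "noise_spec")
}

#' Gamma shape matching a target noise standard deviation
#'
#' Solves `sqrt(k)/(k - 1) = sd` for the shape `k` of the mode-1 gamma
#' factor, i.e. the shape whose multiplicative noise has the requested
#' standard deviation.  Used to construct the high-noise benchmark variant
#' (`sd = 0.03`).
#'
#' @param sd Target standard deviation of the noise factor (0 < sd < 1).
#' @return The gamma shape `k`.
#' @export
gamma_shape_for_sd <- function(sd) {
  if (sd <= 0 || sd >= 1) stop("`sd` must be in (0, 1)", call. = FALSE)
  ## sd^2 (k - 1)^2 = k  =>  sd^2 k^2 - (2 sd^2 + 1) k + sd^2 = 0
  s2 <- sd^2
  (2 * s2 + 1 + sqrt((2 * s2 + 1)^2 - 4 * s2^2)) / (2 * s2)
}

#' Nontrivial Lotka-Volterra steady state
#'
#' Solves `a + B x = 0` for the interior fixed point of the gLV system.
#'
#' @param params An [lv_params] object with nonsingular interaction matrix.
#' @return Steady-state abundance vector.
#' @export
lv_steady_state <- function(params) {
  B <- params$interactions
  qrB <- qr(B)
  if (qrB$rank < nrow(B)) {
    stop(sprintf("interaction matrix is rank deficient (rank %d of %d): no unique steady state",
                 qrB$rank, nrow(B)), call. = FALSE)
  }
  xs <- drop(solve(qrB, -params$growth_rates))
  names(xs) <- params$species
  xs
}

#' MAR(1) fixed point
#'
#' Solves `x = alpha + beta x`, i.e. `x = (I - beta)^{-1} alpha`.
#'
#' @param params A [mar_params] object with `I - beta` nonsingular.
#' @return Fixed-point state vector (model scale).
#' @export
mar_steady_state <- function(params) {
  n <- length(params$intercepts)
  M <- diag(n) - params$transition
  qrM <- qr(M)
  if (qrM$rank < n) {
    stop("I - beta is singular: no unique fixed point", call. = FALSE)
  }
  xs <- drop(solve(qrM, params$intercepts))
  names(xs) <- params$species
  xs
}

#' Steady-state-equivalent MAR model of an LV system
#'
#' LV and MAR(1) share their steady-state equations: with `alpha = a`,
#' off-diagonal `beta_ij = b_ij` and diagonal `beta_ii = b_ii + 1`, the MAR
#' fixed point coincides with the LV interior steady state.  The returned
#' model is deterministic (zero process covariance).
#'
#' @param params An [lv_params] object.
#' @return A [mar_params] object with the same steady state.
#' @export
lv_to_mar_steady_map <- function(params) {
  beta <- params$interactions + diag(nrow(params$interactions))
  mar_params(params$growth_rates, beta, species = params$species)
}
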