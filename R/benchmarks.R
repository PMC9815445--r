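#' Synthetic benchmark scenario specification
#'
#' A fully deterministic recipe for generating a benchmark dataset: the
#' model family, its parameters, the initial state, the simulation grid,
#' the noise setting and the default sampling scheme.  A spec plus a seed
#' regenerates its dataset exactly.
#'
#' @param kind `"lv"` or `"mar"`.
#' @param params [lv_params] or [mar_params] (for MAR the process
#'   covariance carries the noise).
#' @param x0 Initial state (abundance scale for LV, log-abundance scale for
#'   the Gompertz MAR system).
#' @param grid A [sim_grid].
#' @param noise A [noise_spec] (LV process noise; ignored for MAR).
#' @param sampling Default sampling scheme: `"noisy"`, `"replicate"` or
#'   `"none"`.
#' @param seed Default integer seed.
#' @return An object of class `"scenario_spec"`.
#' @export
scenario_spec <- function(kind = c("lv", "mar"), params, x0, grid,
                          noise = noise_spec(enabled = FALSE),
                          sampling = c("noisy", "replicate", "none"),
                          seed = 1L) {
  kind <- match.arg(kind)
  sampling <- match.arg(sampling)
  structure(list(kind = kind, params = params, x0 = as.numeric(x0),
                 grid = grid, noise = noise, sampling = sampling,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> %s, %d species, %d grid points, sampling: %s\n",
              x$kind, length(x$params$species), x$grid$n_steps + 1L,
              x$sampling))
  invisible(x)
}

#' Four-species Lotka-Volterra benchmark system
#'
#' The default LV benchmark: four species on a 100-point grid over
#' `t in [0, 30]`.  Species 1-3 interact with mixed competition and
#' facilitation signs; species 4 is an intentionally decoupled logistic
#' population (zero off-diagonal row and column) included to probe whether
#' inference detects the detachment.  The interior steady state is positive
#' (about 0.97, 1.39, 1.64, 2.0) and stable.  Process noise is a mode-1
#' gamma factor with shape 10000 (factor sd about 0.01); the high-noise
#' variant lowers the shape until the factor sd is 0.03.
#'
#' @param seed Default seed stored in the spec.
#' @param high_noise Use the sd-0.03 gamma shape instead of 10000.
#' @return A `"scenario_spec"` of kind `"lv"`.
#' @export
make_lv_benchmark <- function(seed = 1L, high_noise = FALSE) {
  a <- c(0.6, 0.9, 0.7, 0.8)
  B <- rbind(c(-0.50, -0.20,  0.10,  0.00),
             c(-0.15, -0.60,  0.05,  0.00),
             c( 0.10, -0.10, -0.40,  0.00),
             c( 0.00,  0.00,  0.00, -0.40))
  params <- lv_params(a, B)
  shape <- if (high_noise) gamma_shape_for_sd(0.03) else 10000
  scenario_spec("lv", params, x0 = c(0.3, 0.4, 0.5, 0.1),
                grid = span_grid(0, 30, 100),
                noise = noise_spec(shape = shape, enabled = TRUE),
                sampling = "noisy", seed = seed)
}

#' Four-species MAR(1) benchmark system
#'
#' The default MAR benchmark: a four-species Gompertz (log-abundance)
#' MAR(1) system with a fully dense transition matrix (16 nonzero entries,
#' so the sign-recovery series-length criterion asks for 80 points),
#' spectral radius about 0.66, fixed point `(1.5, 1.2, 1.0, 0.8)` on the
#' log scale, and isotropic process noise of sd 0.1 per step.  The default
#' series length is 31 points.
#'
#' @param seed Default seed stored in the spec.
#' @param noise_sd Per-step process-noise standard deviation (log scale).
#' @return A `"scenario_spec"` of kind `"mar"`.
#' @export
make_mar_benchmark <- function(seed = 1L, noise_sd = 0.1) {
  beta <- rbind(c( 0.50,  0.10, -0.10,  0.05),
                c( 0.08,  0.60,  0.05, -0.10),
                c(-0.05,  0.10,  0.55,  0.08),
                c( 0.10, -0.08,  0.06,  0.50))
  xstar <- c(1.5, 1.2, 1.0, 0.8)          # log-abundance fixed point
  alpha <- drop((diag(4) - beta) %*% xstar)
  params <- mar_params(alpha, beta, diag(noise_sd^2, 4))
  scenario_spec("mar", params, x0 = log(c(0.3, 0.5, 0.4, 0.2)),
                grid = sim_grid(0, 1, 30), sampling = "noisy", seed = seed)
}

#' Simulate a benchmark scenario (with noise)
#'
#' LV scenarios run the Euler-discretized simulator with multiplicative
#' gamma process noise; MAR scenarios run the stochastic recursion on the
#' log scale and return exponentiated (abundance-scale) values.
#'
#' @param spec A [scenario_spec].
#' @param seed Integer seed; defaults to the spec's.
#' @return A [trajectory] on abundance scale.
#' @export
simulate_scenario <- function(spec, seed = spec$seed) {
  if (spec$kind == "lv") {
    ## the noise-free system is the ODE itself; the Euler discretization
    ## exists only to inject per-step process noise
    if (!spec$noise$enabled) return(scenario_truth(spec))
    simulate_lv_discrete(spec$params, spec$x0, spec$grid,
                         noise = spec$noise, seed = seed)
  } else {
    tr <- simulate_mar(spec$params, spec$x0, n_steps = spec$grid$n_steps,
                       seed = seed, start_time = spec$grid$start_time,
                       step = spec$grid$step)
    trajectory(tr$times, exp(tr$values), species = tr$species)
  }
}

#' Noise-free truth of a benchmark scenario
#'
#' LV: the continuous ODE solution on the scenario grid.  MAR: the
#' deterministic recursion, exponentiated to abundance scale.
#'
#' @param spec A [scenario_spec].
#' @return A [trajectory] on abundance scale.
#' @export
scenario_truth <- function(spec) {
  if (spec$kind == "lv") {
    simulate_lv_ode(spec$params, spec$x0, spec$grid)
  } else {
    tr <- simulate_mar(spec$params, spec$x0, n_steps = spec$grid$n_steps,
                       deterministic = TRUE,
                       start_time = spec$grid$start_time,
                       step = spec$grid$step)
    trajectory(tr$times, exp(tr$values), species = tr$species)
  }
}

#' Randomly subsample a trajectory ("noisy" sampling)
#'
#' Uniform random subset of `n` time points without replacement, order
#' preserved.
#'
#' @param traj A [trajectory].
#' @param n Number of points to keep (default 40).
#' @param seed Integer seed.
#' @return An [abundance_data].
#' @export
sample_noisy <- function(traj, n = 40, seed = NULL) {
  if (n > length(traj$times)) {
    stop(sprintf("cannot sample %d of %d points", n, length(traj$times)),
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  idx <- sort(sample.int(length(traj$times), n))
  abundance_data(traj$times[idx], traj$values[idx, , drop = FALSE],
                 species = traj$species)
}

## 15 replicate time points: local extrema of the noise-free trajectory
## ("including extremes") plus equispaced fill.
pick_replicate_times <- function(truth, n_points = 15) {
  m <- length(truth$times)
  ext <- integer(0)
  for (j in seq_len(ncol(truth$values))) {
    d <- diff(truth$values[, j])
    turn <- which(d[-1] * d[-length(d)] < 0) + 1L
    ext <- union(ext, turn)
  }
  ext <- union(ext, c(1L, m))
  if (length(ext) > n_points) {
    ext <- ext[round(seq(1, length(ext), length.out = n_points))]
  }
  fill <- round(seq(1, m, length.out = n_points))
  idx <- sort(union(ext, fill))
  if (length(idx) > n_points) {
    idx <- sort(ext)
    extra <- setdiff(fill, ext)
    idx <- sort(c(idx, extra[seq_len(n_points - length(idx))]))
  }
  sort(unique(idx))[seq_len(min(n_points, length(unique(idx))))]
}

#' Replicated sampling of a benchmark scenario
#'
#' Runs `n_replicates` independent stochastic simulations of the scenario
#' and records each at a fixed set of time points (default: 15 points
#' chosen as local extrema of the noise-free trajectory plus equispaced
#' fill), labelling the rows by replicate.
#'
#' @param spec A [scenario_spec].
#' @param timepoints Explicit times on the scenario grid, or `NULL` for the
#'   default choice.
#' @param n_replicates Number of independent runs (default 5).
#' @param seed Base integer seed; replicate `r` uses `seed + r`.
#' @return An [abundance_data] with replicate labels
#'   (`length(timepoints) * n_replicates` rows).
#' @export
sample_replicates <- function(spec, timepoints = NULL, n_replicates = 5,
                              seed = spec$seed) {
  truth <- scenario_truth(spec)
  if (is.null(timepoints)) {
    idx <- pick_replicate_times(truth, 15)
  } else {
    idx <- match_times(timepoints, truth$times)
  }
  tt <- truth$times[idx]
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    tr <- simulate_scenario(spec, seed = seed + r)
    rows[[r]] <- data.frame(time = tt, replicate = paste0("rep", r),
                            tr$values[idx, , drop = FALSE],
                            check.names = FALSE)
  }
  as_abundance_data(do.call(rbind, rows))
}

## The canonical four-species competitive chaotic LV system, rescaled in
## time (x3) and abundance (x3) so that twin divergence and attractor size
## are resolvable on the benchmark window; `r_mult` perturbs the growth
## rates to reach the neighbouring periodic (limit-cycle) and alternative
## chaotic regimes.
chaotic_lv <- function(r_mult = c(1, 1, 1, 1)) {
  r <- c(1, 0.72, 1.53, 1.27) * r_mult
  A <- rbind(c(1.00, 1.09, 1.52, 0.00),
             c(0.00, 1.00, 0.44, 1.36),
             c(2.33, 0.00, 1.00, 0.47),
             c(1.21, 0.51, 0.35, 1.00))
  list(params = lv_params(3 * r, -(r * A)),
       x0 = 3 * c(0.301, 0.459, 0.131, 0.356))
}

#' Six-regime dynamics suite
#'
#' Six noise-free LV systems spanning qualitatively different dynamics:
#' convergence to a stable steady state, damped oscillations, erratic
#' transients converging to a limit cycle, sustained (neutral)
#' oscillations, and two chaotic systems.  Each entry carries a fit window
#' `t in [1, 100]` (100 grid points), an extrapolation horizon `t = 500`,
#' and the default algebraic-inference sampling times (5, 10, 20, 30, 50;
#' 4, 6, 10, 15, 35 for the chaotic systems).
#'
#' @return Named list of six `"scenario_spec"` objects with extra fields
#'   `fit_window`, `extrapolate_to` and `sample_times`.
#' @export
dynamics_suite <- function() {
  base_times <- c(5, 10, 20, 30, 50)
  chaos_times <- c(4, 6, 10, 15, 35)
  mk <- function(name, params, x0, sample_times = base_times) {
    sp <- scenario_spec("lv", params, x0, grid = span_grid(1, 100, 100),
                        noise = noise_spec(enabled = FALSE),
                        sampling = "none")
    sp$fit_window <- c(1, 100)
    sp$extrapolate_to <- 500
    sp$sample_times <- sample_times
    sp$regime <- name
    sp
  }
  stable <- mk("stable",
               lv_params(c(1, 1), rbind(c(-1, -0.5), c(-0.5, -1))),
               c(0.2, 0.3))
  damped <- mk("damped",
               lv_params(c(1, -1), rbind(c(-0.05, -0.5), c(0.5, -0.05))),
               c(0.5, 0.5))
  lc <- chaotic_lv(r_mult = c(1, 1, 0.90, 1))
  limit_cycle <- mk("limit_cycle", lc$params, lc$x0)
  sustained <- mk("sustained",
                  lv_params(c(1, -1), rbind(c(0, -0.5), c(0.5, 0))),
                  c(1, 1))
  c1 <- chaotic_lv()
  chaos1 <- mk("chaos1", c1$params, c1$x0, chaos_times)
  c2 <- chaotic_lv(r_mult = c(1.1, 1, 1, 1))
  chaos2 <- mk("chaos2", c2$params, c2$x0, chaos_times)
  list(stable = stable, damped = damped, limit_cycle = limit_cycle,
       sustained = sustained, chaos1 = chaos1, chaos2 = chaos2)
}

#' Initial states scaled off the steady state
#'
#' The system's nontrivial steady state elementwise-scaled by each
#' multiplier.  For the Gompertz MAR system the scaling acts on abundance
#' scale (the log-scale state is shifted by `log(multiplier)`).
#'
#' @param spec A [scenario_spec], [lv_params] or [mar_params].
#' @param multipliers Numeric multipliers
#'   (default `c(0.001, 0.01, 0.1, 1.9, 10, 100)`).
#' @return Named list of initial states (model scale), one per multiplier.
#' @export
initial_condition_grid <- function(spec,
                                   multipliers = c(0.001, 0.01, 0.1, 1.9, 10, 100)) {
  if (inherits(spec, "lv_params")) {
    xs <- lv_steady_state(spec)
    out <- lapply(multipliers, function(m) xs * m)
  } else if (inherits(spec, "mar_params")) {
    xs <- mar_steady_state(spec)
    out <- lapply(multipliers, function(m) xs + log(m))
  } else if (inherits(spec, "scenario_spec")) {
    return(initial_condition_grid(spec$params, multipliers))
  } else {
    stop("unsupported system specification", call. = FALSE)
  }
  names(out) <- as.character(multipliers)
  out
}

#' Assemble a named benchmark comparison scenario
#'
#' Generates one of the four standard benchmark datasets — LV or MAR
#' system, noisy or replicate sampling — together with its noise-free truth
#' and the per-scenario defaults (smoothing df, grid step) used by
#' [run_comparison()].  The LV noisy dataset samples 40 random points from
#' the 100-point noisy run; the MAR noisy dataset keeps its full 31-point
#' noisy series; replicate datasets record 15 fixed points in 5 independent
#' runs.
#'
#' @param name One of `"lv-noisy"`, `"lv-replicate"`, `"mar-noisy"`,
#'   `"mar-replicate"`.
#' @param seed Integer seed.
#' @param high_noise Use the high-noise LV variant.
#' @param df Smoothing df override; defaults are 8 (LV), 15 (MAR noisy) and
#'   11 (MAR replicate).
#' @return A scenario bundle (list) for [run_comparison()].
#' @export
benchmark_scenario <- function(name = c("lv-noisy", "lv-replicate",
                                        "mar-noisy", "mar-replicate"),
                               seed = 1L, high_noise = FALSE, df = NULL) {
  name <- match.arg(name)
  kind <- if (startsWith(name, "lv")) "lv" else "mar"
  spec <- if (kind == "lv") make_lv_benchmark(seed, high_noise) else
    make_mar_benchmark(seed)
  truth <- scenario_truth(spec)
  if (name == "lv-noisy") {
    data <- sample_noisy(simulate_scenario(spec, seed = seed), n = 40,
                         seed = seed + 1L)
  } else if (name == "mar-noisy") {
    data <- as_abundance_data(simulate_scenario(spec, seed = seed))
  } else {
    data <- sample_replicates(spec, n_replicates = 5, seed = seed)
  }
  if (is.null(df)) {
    df <- switch(name, "lv-noisy" = 8, "lv-replicate" = 8,
                 "mar-noisy" = 15, "mar-replicate" = 11)
  }
  list(name = name, data = data, truth = truth, reference = "truth",
       df = df, step = spec$grid$step, seed = seed + 2L, spec = spec)
}
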