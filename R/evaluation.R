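## Match observation times against prediction times (exact up to rounding).
match_times <- function(times, ref_times, tol = NULL) {
  if (is.null(tol)) tol <- 1e-6 * max(1, diff(range(ref_times)))
  idx <- vapply(times, function(t) {
    j <- which.min(abs(ref_times - t))
    if (abs(ref_times[j] - t) > tol) NA_integer_ else j
  }, integer(1))
  if (any(is.na(idx))) {
    stop(sprintf("time mismatch: prediction not evaluable at t = %g",
                 times[which(is.na(idx))[1]]), call. = FALSE)
  }
  idx
}

#' Sum of squared errors of a prediction against observations
#'
#' Squared residuals summed over all observations, per species and in
#' total.  Replicated observations each contribute their own residual;
#' missing entries are skipped.  The prediction must be evaluable at every
#' observation time.
#'
#' @param pred A predicted [trajectory].
#' @param obs Observed [abundance_data] (or coercible).
#' @return List with `per_species` (named vector) and `total`.
#' @export
sse <- function(pred, obs) {
  obs <- as_abundance_data(obs)
  idx <- match_times(obs$times, pred$times)
  resid <- obs$values - pred$values[idx, , drop = FALSE]
  per <- colSums(resid^2, na.rm = TRUE)
  names(per) <- obs$species
  list(per_species = per, total = sum(per))
}

#' Mean-normalized sum of squared errors
#'
#' Residuals are divided by the per-species observed mean before squaring,
#' balancing the SSE across species whose abundances differ by orders of
#' magnitude.
#'
#' @inheritParams sse
#' @return List with `per_species` and `total`.
#' @export
normalized_sse <- function(pred, obs) {
  obs <- as_abundance_data(obs)
  mu <- colMeans(obs$values, na.rm = TRUE)
  if (any(mu == 0)) stop("species with zero observed mean: cannot normalize",
                         call. = FALSE)
  idx <- match_times(obs$times, pred$times)
  resid <- sweep(obs$values - pred$values[idx, , drop = FALSE], 2, mu, `/`)
  per <- colSums(resid^2, na.rm = TRUE)
  names(per) <- obs$species
  list(per_species = per, total = sum(per))
}

#' SSE over the final points of two trajectories
#'
#' Restricts the SSE to the last `n_last` grid times of the reference
#' trajectory — a check of whether a fit captures the system's eventual
#' (steady-state) behaviour.
#'
#' @param pred Predicted [trajectory].
#' @param truth Reference (noise-free) [trajectory].
#' @param n_last Number of final time points (default 5).
#' @return Total SSE over the final `n_last` points.
#' @export
tail_sse <- function(pred, truth, n_last = 5) {
  if (length(truth$times) < n_last || length(pred$times) < n_last) {
    stop(sprintf("both series must cover the last %d grid times", n_last),
         call. = FALSE)
  }
  tt <- utils::tail(truth$times, n_last)
  idx <- match_times(tt, pred$times)
  sum((truth$values[match_times(tt, truth$times), , drop = FALSE] -
         pred$values[idx, , drop = FALSE])^2)
}

#' Count sign flips between estimated and true coefficients
#'
#' Number of entries whose estimated sign is strictly opposite to the true
#' sign (product < 0).  Zeros on either side are sign-neutral and never
#' count.
#'
#' @param estimated,truth Numeric matrices (or vectors) of the same shape.
#' @return Integer count.
#' @export
sign_flip_count <- function(estimated, truth) {
  estimated <- as.matrix(estimated); truth <- as.matrix(truth)
  if (!all(dim(estimated) == dim(truth))) {
    stop("shape mismatch between estimated and true coefficients", call. = FALSE)
  }
  sum(estimated * truth < 0)
}

#' Minimum series length for sign recovery
#'
#' The rule of thumb that a MAR time series should be at least 5 times
#' longer than the number of a-priori nonzero entries of the transition
#' matrix for interaction signs to be recoverable.
#'
#' @param beta Transition matrix (or a [mar_params]).
#' @return `5 *` number of nonzero entries of `beta`.
#' @export
min_series_length <- function(beta) {
  if (inherits(beta, "mar_params")) beta <- beta$transition
  5L * sum(beta != 0)
}

#' Paired Wilcoxon signed-rank comparison of two SSE vectors
#'
#' Two-sided Wilcoxon signed-rank test on paired differences, zero
#' differences dropped.  For 25 or fewer nonzero pairs the exact null
#' distribution of the signed-rank statistic is used (computed by a
#' convolution over the tied midranks, so ties are handled exactly rather
#' than by approximation); above that, the normal approximation of
#' [stats::wilcox.test()].
#'
#' @param sse_a,sse_b Equal-length vectors of per-scenario SSEs.
#' @return List with `statistic` (the positive-rank sum V), `p_value` and
#'   `n_used` (nonzero pairs).
#' @export
wilcoxon_compare <- function(sse_a, sse_b) {
  if (length(sse_a) != length(sse_b)) {
    stop("vectors must have equal length (paired by scenario)", call. = FALSE)
  }
  d <- sse_a - sse_b
  d <- d[d != 0]
  if (length(d) == 0) stop("all paired differences are zero", call. = FALSE)
  m <- length(d)
  r <- rank(abs(d))                       # midranks under ties
  v <- sum(r[d > 0])
  if (m <= 25) {
    ## exact null: V = sum of a uniform random subset of the midranks.
    ## Work on doubled ranks so tied midranks stay integral.
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    f <- numeric(tot + 1); f[1] <- 1      # f[k+1] = #subsets with sum k
    for (ri in r2) {
      shifted <- c(numeric(ri), f[seq_len(tot + 1 - ri)])
      f <- f + shifted
    }
    probs <- f / 2^m
    v2 <- round(2 * v)
    p_le <- sum(probs[seq_len(v2 + 1)])
    p_ge <- sum(probs[(v2 + 1):(tot + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(d, exact = FALSE, correct = FALSE,
                         alternative = "two.sided"))
    p <- wt$p.value
  }
  list(statistic = v, p_value = p, n_used = m)
}

## ---- comparison harness --------------------------------------------------

mar_free_run_times <- function(params, x0, times) {
  n <- length(params$intercepts)
  out <- matrix(NA_real_, length(times), n)
  out[1, ] <- x0
  x <- x0
  for (s in seq_len(length(times) - 1L)) {
    x <- drop(params$intercepts + params$transition %*% x)
    out[s + 1L, ] <- x
  }
  trajectory(times, out, species = params$species)
}

## Fit one method on one comparison scenario.  Returns the fitted params,
## the full-grid prediction (abundance scale) and the SSE against the
## scenario's reference, or an Inf SSE with the failure reason.
fit_comparison_method <- function(method, scenario, config) {
  tryCatch({
    data <- scenario$data
    ref <- scenario$ref_data       # precomputed reference series
    grid_t <- scenario$grid_times  # full grid (>= first observation)
    if (method %in% c("alvi-lr", "alvi-mi")) {
      sm <- fit_spline(data, df = scenario$df)
      x0 <- pmax(eval_smooth(sm, grid_t[1])$values[1, ], 1e-8)
      if (method == "alvi-lr") {
        pool <- resample_spline(sm, n = config$pool_n)
        keep <- rowSums(pool$values <= 0) == 0
        pool <- slope_points(pool$times[keep],
                             pool$values[keep, , drop = FALSE],
                             pool$slopes[keep, , drop = FALSE])
        est <- alvi_lr(pool)
      } else {
        ens <- subsample_search(sm, data, strategy = "monte_carlo",
                                n_iter = config$mi_iters,
                                seed = scenario$seed,
                                reference = scenario$reference,
                                truth = scenario$truth,
                                pool_n = config$pool_n)
        best <- which(is.finite(ens$results$sse))[1]
        if (is.na(best)) stop("all ALVI-MI candidates failed: ",
                              ens$results$reason[1])
        est <- ens$fits[[best]]$params
      }
      pred <- simulate_lv_ode_at(est, x0, grid_t)
      s <- sse(pred, ref)
      list(params = est, pred = pred, sse = s$total,
           per_species = s$per_species, space = "lv", reason = NULL)
    } else {
      use_log <- method %in% c("mar-log", "mar-log-smooth")
      use_smooth <- method %in% c("mar-smooth", "mar-log-smooth")
      pt <- prepare_transform(data, log = use_log,
                              smooth_df = if (use_smooth) scenario$df else NULL)
      est <- fit_mar(pt$data, step = scenario$step)
      first <- pt$data$values[which.min(pt$data$times), ]
      run_t <- grid_t[grid_t >= min(pt$data$times) - 1e-9]
      pred_t <- mar_free_run_times(est, first, run_t)
      pred <- back_transform(pred_t, pt$record)
      ref_use <- restrict_data(ref, min(run_t))
      s <- sse(pred, ref_use)
      list(params = est, pred = pred, sse = s$total,
           per_species = s$per_species,
           space = if (use_log) "mar-log" else "mar", reason = NULL)
    }
  }, error = function(e) {
    list(params = NULL, pred = NULL, sse = Inf, per_species = NULL,
         space = NA_character_, reason = conditionMessage(e))
  })
}

restrict_data <- function(data, t_min) {
  keep <- data$times >= t_min - 1e-9
  abundance_data(data$times[keep], data$values[keep, , drop = FALSE],
                 species = data$species,
                 replicate = if (is.null(data$replicate)) NULL else
                   data$replicate[keep])
}

## Normalize a scenario bundle for the harness: attach reference series,
## full grid times and per-scenario defaults.
prepare_scenario <- function(scenario, config) {
  stopifnot(!is.null(scenario$name), !is.null(scenario$data))
  if (is.null(scenario$reference)) {
    scenario$reference <- if (is.null(scenario$truth)) "data" else "truth"
  }
  if (is.null(scenario$df)) scenario$df <- config$df
  if (is.null(scenario$seed)) scenario$seed <- config$seed
  data <- as_abundance_data(scenario$data)
  scenario$data <- data
  if (scenario$reference == "truth") {
    ref <- as_abundance_data(scenario$truth)
  } else {
    ref <- average_replicates(data)
  }
  t_first <- min(data$times)
  scenario$ref_data <- restrict_data(ref, t_first)
  if (!is.null(scenario$truth)) {
    scenario$grid_times <- scenario$truth$times[scenario$truth$times >= t_first - 1e-9]
  } else {
    g <- snap_to_grid(data$times, scenario$step)
    scenario$grid_times <- g$t0 + g$step * (min(g$idx):max(g$idx))
  }
  if (is.null(scenario$step)) {
    scenario$step <- min(diff(sort(unique(scenario$grid_times))))
  }
  scenario
}

#' Run the scenario-by-method SSE comparison
#'
#' Fits every requested method on every scenario, scores each fit against
#' the scenario's reference series, and returns the comparison table with
#' the per-row minimum marked.  A method failure is recorded as an infinite
#' SSE with its reason; it never aborts the table.
#'
#' @param scenarios A list of scenario bundles (e.g. from
#'   [benchmark_scenario()]): each a list with `name`, `data`, optional
#'   `truth` (noise-free [trajectory]), `reference` (`"truth"`, `"data"` or
#'   `"smooth"`), `df`, `step`, `seed`.
#' @param methods Subset of `c("alvi-lr", "alvi-mi", "mar", "mar-log",
#'   "mar-smooth", "mar-log-smooth")`.
#' @param config List of harness settings: `pool_n` (spline resampling pool
#'   size, default 50), `mi_iters` (Monte-Carlo ALVI-MI draws, default 200),
#'   `df` (fallback smoothing df, default 8), `seed` (fallback seed).
#' @return An object of class `"sse_table"`: a data.frame with one row per
#'   scenario, one SSE column per method, and a `best_method` column;
#'   attributes `reference` (per row), `failures` (reasons) and `manifest`
#'   (settings and seeds sufficient to reproduce the table).
#' @export
run_comparison <- function(scenarios,
                           methods = c("alvi-lr", "alvi-mi", "mar", "mar-log",
                                       "mar-smooth", "mar-log-smooth"),
                           config = list()) {
  allowed <- c("alvi-lr", "alvi-mi", "mar", "mar-log", "mar-smooth",
               "mar-log-smooth")
  if (!all(methods %in% allowed)) {
    stop("unknown method(s): ", paste(setdiff(methods, allowed), collapse = ", "),
         call. = FALSE)
  }
  defaults <- list(pool_n = 50, mi_iters = 200, df = 8, seed = 1L)
  config <- utils::modifyList(defaults, config)
  tab <- matrix(NA_real_, length(scenarios), length(methods),
                dimnames = list(vapply(scenarios, `[[`, "", "name"), methods))
  failures <- list()
  refs <- character(length(scenarios))
  fits <- list()
  for (i in seq_along(scenarios)) {
    sc <- prepare_scenario(scenarios[[i]], config)
    refs[i] <- sc$reference
    for (m in methods) {
      res <- fit_comparison_method(m, sc, config)
      tab[i, m] <- res$sse
      if (!is.null(res$reason)) {
        failures[[paste(sc$name, m, sep = "/")]] <- res$reason
      }
      fits[[paste(sc$name, m, sep = "/")]] <- res
    }
  }
  best <- apply(tab, 1, function(r) {
    if (all(!is.finite(r))) NA_character_ else methods[which.min(r)]
  })
  out <- data.frame(scenario = rownames(tab), tab, best_method = best,
                    check.names = FALSE, row.names = NULL)
  manifest <- list(tool = "lvmar", version = as.character(utils::packageVersion("lvmar")),
                   methods = methods, config = config,
                   scenario_seeds = vapply(scenarios, function(s)
                     as.integer(if (is.null(s$seed)) config$seed else s$seed), 1L),
                   reference = refs)
  structure(out, class = c("sse_table", "data.frame"),
            reference = refs, failures = failures, manifest = manifest,
            fits = fits)
}

#' @export
print.sse_table <- function(x, ...) {
  cat("SSE comparison (row minima in `best_method`):\n")
  print.data.frame(x, digits = 6)
  invisible(x)
}

#' Initial-condition sweep of both frameworks
#'
#' Starts a benchmark system from its steady state scaled by each
#' multiplier, generates noisy (40 random points of the grid) and/or
#' replicate (15 fixed points x 5 runs) datasets, fits each method, and
#' collects three metrics per multiplier x sampling x method: SSE against
#' the noise-free truth, the steady-state tail SSE over the final 5 grid
#' points, and the interaction sign-flip count (only where the method's
#' parameter space matches the generating system's).
#'
#' @param spec A benchmark [scenario_spec] ([make_lv_benchmark()] or
#'   [make_mar_benchmark()]).
#' @param multipliers Steady-state multipliers (default
#'   `c(0.001, 0.01, 0.1, 1.9, 10, 100)`).
#' @param sampling Which sampling schemes to run.
#' @param methods As in [run_comparison()].
#' @param seed Base integer seed.
#' @param config Harness config, as in [run_comparison()].
#' @return List of three data.frames — `sse`, `tail_sse`, `sign_flips` —
#'   with one row per multiplier x sampling and one column per method.
#' @export
initial_condition_sweep <- function(spec,
                                    multipliers = c(0.001, 0.01, 0.1, 1.9, 10, 100),
                                    sampling = c("noisy", "replicate"),
                                    methods = c("alvi-lr", "alvi-mi", "mar",
                                                "mar-log", "mar-smooth",
                                                "mar-log-smooth"),
                                    seed = 1L, config = list()) {
  sampling <- match.arg(sampling, several.ok = TRUE)
  defaults <- list(pool_n = 50, mi_iters = 200, df = 8)
  config <- utils::modifyList(defaults, config)
  states <- initial_condition_grid(spec, multipliers)
  rows <- expand.grid(multiplier = multipliers, sampling = sampling,
                      stringsAsFactors = FALSE)
  mk <- function() {
    d <- as.data.frame(matrix(NA_real_, nrow(rows), length(methods),
                              dimnames = list(NULL, methods)))
    cbind(rows, d)
  }
  out <- list(sse = mk(), tail_sse = mk(), sign_flips = mk())
  for (r in seq_len(nrow(rows))) {
    mult <- rows$multiplier[r]
    samp <- rows$sampling[r]
    sp <- spec
    sp$x0 <- states[[as.character(mult)]]
    row_seed <- seed + 1000L * r
    truth <- scenario_truth(sp)
    data <- tryCatch({
      if (samp == "noisy") {
        sample_noisy(simulate_scenario(sp, seed = row_seed), n = 40,
                     seed = row_seed + 1L)
      } else {
        sample_replicates(sp, n_replicates = 5, seed = row_seed)
      }
    }, error = function(e) NULL)
    if (is.null(data)) next
    sc <- prepare_scenario(list(name = sprintf("%s-x%g", samp, mult),
                                data = data, truth = truth,
                                reference = "truth", df = config$df,
                                step = spec$grid$step, seed = row_seed + 2L),
                           config)
    for (m in methods) {
      res <- fit_comparison_method(m, sc, config)
      out$sse[r, m] <- res$sse
      if (!is.null(res$pred)) {
        out$tail_sse[r, m] <- tryCatch(tail_sse(res$pred, truth, 5),
                                       error = function(e) NA_real_)
      }
      out$sign_flips[r, m] <- sweep_sign_flips(res, sp)
    }
  }
  out
}

## Sign flips are only meaningful when the fitted parameter space matches
## the generating system's: LV estimates vs an LV system, log-scale MAR
## estimates vs a (Gompertz, log-scale) MAR system.
sweep_sign_flips <- function(res, spec) {
  if (is.null(res$params)) return(NA_real_)
  if (spec$kind == "lv" && res$space == "lv") {
    est <- cbind(res$params$growth_rates, res$params$interactions)
    tru <- cbind(spec$params$growth_rates, spec$params$interactions)
    return(sign_flip_count(est, tru))
  }
  if (spec$kind == "mar" && identical(res$space, "mar-log")) {
    est <- cbind(res$params$intercepts, res$params$transition)
    tru <- cbind(spec$params$intercepts, spec$params$transition)
    return(sign_flip_count(est, tru))
  }
  NA_real_
}
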