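# Shared fixtures built in code.

# single-species logistic: a = 1, b = -0.5, carrying capacity 2
logistic_params <- function() lv_params(1, matrix(-0.5))

logistic_data <- function(n = 30, t_max = 8, x0 = 1) {
  as_abundance_data(simulate_lv_ode(logistic_params(), x0, span_grid(0, t_max, n)))
}

# random stable-ish LV system with negative diagonal (seeded by caller)
random_lv <- function(n = 3) {
  a <- stats::runif(n, 0.5, 1.5)
  B <- matrix(stats::runif(n * n, -0.3, 0.3), n, n)
  diag(B) <- -stats::runif(n, 0.5, 1.2)
  lv_params(a, B)
}

max_abs <- function(x) max(abs(x))

# relative error against truth, absolute where truth is zero
mixed_err <- function(est, truth, zero_tol = 0) {
  err <- abs(est - truth)
  nz <- truth != 0
  err[nz] <- err[nz] / abs(truth[nz])
  err
}

lv_param_matrix <- function(p) cbind(p$growth_rates, p$interactions)
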