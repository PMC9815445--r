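test_that("the transform pipeline applies and records each step", {
  d <- abundance_data(rep(0:4, 2),
                      cbind(A = c(1, 2, 3, 4, 5, 3, 4, 5, 6, 7),
                            B = rep(2, 10)),
                      replicate = rep(c("r1", "r2"), each = 5))
  # all-off: just replicate averaging
  pt <- prepare_transform(d)
  expect_equal(unname(pt$data$values[, "A"]), c(2, 3, 4, 5, 6))
  expect_false(pt$record$log_applied)
  # zeros replaced by 1e-5 before the log
  dz <- abundance_data(0:4, matrix(c(0, 1, 2, 1, 3), ncol = 1), species = "A")
  ptz <- prepare_transform(dz, log = TRUE)
  expect_equal(unname(ptz$data$values[1, 1]), log(1e-5))
  expect_equal(ptz$record$zeros_replaced, 1L)
  # z-scored columns have mean 0, sd 1
  dv <- abundance_data(0:4, cbind(A = c(2, 3, 4, 5, 6), B = c(1, 4, 2, 6, 3)))
  ptn <- prepare_transform(dv, zscore = TRUE)
  expect_lt(max_abs(colMeans(ptn$data$values)), 1e-10)
  expect_equal(unname(apply(ptn$data$values, 2, sd)), c(1, 1),
               tolerance = 1e-10)
  # a constant column cannot be z-scored
  expect_error(prepare_transform(d, zscore = TRUE), "constant")
  # negative abundances cannot be logged
  dneg <- abundance_data(0:3, matrix(c(-1, 1, 2, 1), ncol = 1), species = "A")
  expect_error(prepare_transform(dneg, log = TRUE), "negative")
})

test_that("conditional least squares recovers a deterministic recursion", {
  p <- mar_params(c(0.5, 0.2), rbind(c(0.6, 0.1), c(-0.2, 0.7)))
  tr <- simulate_mar(p, c(2, -1), 12, deterministic = TRUE)
  fit <- fit_mar(as_abundance_data(tr))
  expect_lt(max_abs(fit$intercepts - p$intercepts), 1e-10)
  expect_lt(max_abs(fit$transition - p$transition), 1e-10)
  expect_lt(max_abs(fit$process_covariance), 1e-18)
  # constant series: intercept and lag indistinguishable
  const <- abundance_data(0:9, matrix(2, 10, 1), species = "A")
  expect_error(fit_mar(const), "ollinear")
  # too few pairs
  short <- abundance_data(0:2, matrix(c(1, 2, 3), ncol = 1), species = "A")
  expect_error(fit_mar(short), "consecutive-pair")
  # replicates must be averaged first
  dr <- abundance_data(rep(0:4, 2), matrix(rnorm(10) + 5, ncol = 1),
                       species = "A", replicate = rep(c("a", "b"), each = 5))
  expect_error(fit_mar(dr), "average")
})

test_that("CLS estimates sit within their own standard errors", {
  p <- mar_params(1, matrix(0.5), matrix(0.01))
  tr <- simulate_mar(p, 2, 500, seed = 31)
  fit <- fit_mar(as_abundance_data(tr))
  se <- attr(fit, "std_errors")   # 1 x 2: intercept, lag
  expect_lt(abs(fit$intercepts - 1), 3 * se[1, 1])
  expect_lt(abs(fit$transition[1, 1] - 0.5), 3 * se[1, 2])
  expect_equal(fit$process_covariance[1, 1], 0.01, tolerance = 0.3)
})

test_that("gaps contribute no pairs but the fit still succeeds", {
  p <- mar_params(c(0.5, 0.2), rbind(c(0.6, 0.1), c(-0.2, 0.7)))
  tr <- simulate_mar(p, c(2, -1), 30, deterministic = TRUE)
  keep <- setdiff(1:31, c(5, 12, 13, 20))  # punch gaps in the grid
  d <- abundance_data(tr$times[keep], tr$values[keep, ])
  fit <- fit_mar(d)
  expect_lt(max_abs(fit$transition - p$transition), 1e-9)
  expect_equal(attr(fit, "n_pairs"), sum(diff(keep) == 1))
})

test_that("free-run and one-step predictions invert the recursion", {
  p <- mar_params(c(0.5, 0.2), rbind(c(0.6, 0.1), c(-0.2, 0.7)))
  tr <- simulate_mar(p, c(2, -1), 15, deterministic = TRUE)
  d <- as_abundance_data(tr)
  # free run from the truth reproduces the training series
  fr <- predict_mar(p, d, mode = "free_run")
  expect_lt(max_abs(fr$values - tr$values), 1e-12)
  # one-step with true parameters has zero residuals
  os <- predict_mar(p, d, mode = "one_step")
  idx <- match(os$times, tr$times)
  expect_lt(max_abs(os$values - tr$values[idx, ]), 1e-12)
  # contraction: long free run converges to the fixed point
  long <- predict_mar(p, abundance_data(0:1, tr$values[1:2, ]), "free_run")
  fr_long <- lvmar:::mar_free_run_times(p, tr$values[1, ], 0:200)
  expect_lt(max_abs(fr_long$values[201, ] - mar_steady_state(p)), 1e-8)
})

test_that("back-transform inverts the recorded pipeline", {
  d <- abundance_data(0:9, cbind(A = exp(sin(0:9)) + 1, B = (1:10) / 2))
  pt <- prepare_transform(d, log = TRUE, zscore = TRUE)
  round_trip <- back_transform(trajectory(pt$data$times, pt$data$values,
                                          pt$data$species), pt$record)
  expect_lt(max_abs(round_trip$values - d$values), 1e-10)
  # all-off record is the identity
  pt0 <- prepare_transform(d)
  tr <- trajectory(0:1, matrix(c(1, 2), 2))
  expect_equal(back_transform(tr, pt0$record)$values, tr$values)
  # log-space zero maps to abundance 1
  ptl <- prepare_transform(d, log = TRUE)
  tr0 <- trajectory(0:1, matrix(0, 2, 2))
  expect_equal(unname(back_transform(tr0, ptl$record)$values),
               matrix(1, 2, 2))
  expect_error(back_transform(tr, record = list()), "transform_record")
})

test_that("prediction intervals propagate the process covariance", {
  p0 <- mar_params(1, matrix(0.5))
  tr <- simulate_mar(p0, 2, 10, deterministic = TRUE)
  pi0 <- prediction_interval(p0, tr)
  expect_equal(pi0$lower, tr$values)  # zero covariance: zero width
  # beta = 0: half-width qnorm(0.975) * sigma at every step after the first
  sig <- 0.3
  p1 <- mar_params(1, matrix(0), matrix(sig^2))
  tr1 <- simulate_mar(p1, 1, 6, deterministic = TRUE)
  pi1 <- prediction_interval(p1, tr1, level = 0.95)
  half <- (pi1$upper - pi1$lower) / 2
  expect_equal(unname(half[2:7, 1]), rep(qnorm(0.975) * sig, 6),
               tolerance = 1e-12)
  expect_equal(unname(half[1, 1]), 0)
  # width is monotone in a scalar multiplier on delta
  p2 <- mar_params(1, matrix(0.5), matrix(4 * sig^2))
  pi2 <- prediction_interval(p2, tr1, level = 0.95)
  expect_true(all(pi2$upper - pi2$lower >= pi1$upper - pi1$lower - 1e-12))
  expect_error(prediction_interval(p1, tr1, level = 1.2), "level")
})

test_that("z-scoring before the fit leaves noise-free predictions unchanged", {
  ms <- make_mar_benchmark(1)
  d <- as_abundance_data(simulate_mar(ms$params, ms$x0, 30,
                                      deterministic = TRUE))
  pt <- prepare_transform(d, zscore = TRUE)
  pred_z <- back_transform(predict_mar(fit_mar(pt$data), pt$data, "free_run"),
                           pt$record)
  pred_raw <- predict_mar(fit_mar(d), d, "free_run")
  expect_lt(max_abs(pred_z$values - pred_raw$values), 1e-8)
})

test_that("sign recovery improves with series length", {
  ms <- make_mar_benchmark(1)
  mean_flips <- function(T, reps, seed0) {
    mean(vapply(seq_len(reps), function(r) {
      tr <- simulate_mar(ms$params, ms$x0, n_steps = T - 1, seed = seed0 + r)
      fit <- tryCatch(fit_mar(as_abundance_data(tr)),
                      error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      as.numeric(sign_flip_count(fit$transition, ms$params$transition))
    }, 1), na.rm = TRUE)
  }
  flips <- c(mean_flips(20, 60, 1000), mean_flips(80, 60, 2000),
             mean_flips(320, 30, 3000))
  expect_true(all(diff(flips) <= 0))
})
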