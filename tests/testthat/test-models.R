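test_that("parameter constructors validate their invariants", {
  expect_error(lv_params(c(1, 2), matrix(0, 3, 3)), "dimension")
  expect_error(lv_params(1, matrix(c(1, 2), 1)), "square")
  expect_error(lv_params(1, matrix(NaN)), "finite")
  expect_error(mar_params(c(1, 2), diag(2), matrix(c(1, 2, 0, 1), 2)),
               "symmetric")
  expect_error(mar_params(1, matrix(0.5), matrix(-1)), "semi-definite")
  # spectral radius above 1 is allowed (transients are part of the systems)
  expect_s3_class(mar_params(1, matrix(1.5)), "mar_params")
  expect_error(sim_grid(0, step = 0, n_steps = 5), "step")
  expect_error(noise_spec(shape = 1), "shape")
})

test_that("LV ODE simulation matches closed forms", {
  p <- logistic_params()
  # start at carrying capacity: constant
  tr <- simulate_lv_ode(p, 2, sim_grid(0, 0.5, 10))
  expect_lt(max_abs(tr$values - 2), 1e-7)
  # logistic closed form x(t) = K / (1 + (K/x0 - 1) exp(-a t)), K = 2
  tr <- simulate_lv_ode(p, 1, sim_grid(0, log(3) / 8, 8))
  expect_equal(unname(tr$values[9, 1]), 1.5, tolerance = 1e-6)
  # zero dynamics: constant at x0
  p0 <- lv_params(c(0, 0), matrix(0, 2, 2))
  tr <- simulate_lv_ode(p0, c(3, 7), sim_grid(0, 1, 5))
  expect_equal(unname(tr$values[6, ]), c(3, 7))
  expect_error(simulate_lv_ode(p, c(1, 2), sim_grid(0, 1, 5)), "match")
  expect_error(simulate_lv_ode(p, -1, sim_grid(0, 1, 5)), "non-negative")
})

test_that("LV divergence is reported with the last valid time", {
  p <- lv_params(1, matrix(0.5))  # dx/dt = x (1 + 0.5 x): finite-time blowup
  err <- tryCatch(simulate_lv_ode(p, 1, span_grid(0, 10, 50)),
                  error = function(e) e)
  expect_s3_class(err, "lvmar_blowup")
  expect_true(is.finite(err$last_valid_time))
  expect_lt(err$last_valid_time, 10)
})

test_that("discrete LV iteration is Euler's method when noise is off", {
  p <- logistic_params()
  tr <- simulate_lv_discrete(p, 1, sim_grid(0, 0.1, 1))
  expect_equal(unname(tr$values[2, 1]), 1.05)  # 1 + 0.1 * 1 * (1 - 0.5)
  # equals a hand-rolled Euler loop for a 2-species system
  p2 <- lv_params(c(0.5, -0.2), rbind(c(-0.3, 0.1), c(0.2, -0.4)))
  g <- sim_grid(0, 0.05, 40)
  tr2 <- simulate_lv_discrete(p2, c(1, 2), g)
  x <- c(1, 2)
  for (s in 1:40) x <- x + 0.05 * x * (p2$growth_rates + drop(p2$interactions %*% x))
  expect_equal(unname(tr2$values[41, ]), unname(x), tolerance = 1e-12)
})

test_that("discrete LV with noise is seeded-reproducible and positive", {
  p <- make_lv_benchmark()$params
  g <- span_grid(0, 30, 100)
  x0 <- c(0.3, 0.4, 0.5, 0.1)
  ns <- noise_spec(shape = 10000)
  t1 <- simulate_lv_discrete(p, x0, g, noise = ns, seed = 42)
  t2 <- simulate_lv_discrete(p, x0, g, noise = ns, seed = 42)
  expect_identical(t1$values, t2$values)
  t3 <- simulate_lv_discrete(p, x0, g, noise = ns, seed = 43)
  expect_false(identical(t1$values, t3$values))
  expect_error(simulate_lv_discrete(p, x0, g, noise = ns), "seed")
  # positivity under multiplicative noise, across seeds, unless flagged
  for (s in 1:10) {
    tr <- simulate_lv_discrete(p, x0, g, noise = noise_spec(shape = 500),
                               seed = s)
    if (!attr(tr, "clipped")) expect_true(all(tr$values >= 0))
  }
  # increment-placement switch changes the trajectory
  ti <- simulate_lv_discrete(p, x0, g, noise = ns, seed = 42,
                             noise_on = "increment")
  expect_false(identical(t1$values, ti$values))
})

test_that("gamma process noise has mode 1 and the analytic moments", {
  expect_error(draw_process_noise(1, 10), "shape")
  g <- draw_process_noise(7, 500, seed = 1)
  expect_true(all(g > 0))
  # analytic mean k/(k-1); sd sqrt(k)/(k-1)
  k <- 10000
  expect_equal(k / (k - 1) * (k - 1) / k, 1)  # mode (k-1)*scale == 1 exactly
  g <- draw_process_noise(k, 2e5, seed = 2)
  expect_equal(mean(g), k / (k - 1), tolerance = 1e-4)
  expect_equal(sd(g), sqrt(k) / (k - 1), tolerance = 0.02)
  # shape chosen for a target sd reproduces that sd analytically
  ks <- gamma_shape_for_sd(0.03)
  expect_equal(sqrt(ks) / (ks - 1), 0.03, tolerance = 1e-12)
})

test_that("MAR simulation honours fixed points and seeding", {
  # identity recursion with zero intercepts: constant at x0
  p <- mar_params(c(0, 0), diag(2))
  tr <- simulate_mar(p, c(5, -2), 10, deterministic = TRUE)
  expect_equal(unname(tr$values[11, ]), c(5, -2))
  # x0 at the fixed point alpha/(1 - beta) = 2
  p1 <- mar_params(1, matrix(0.5))
  tr <- simulate_mar(p1, 2, 1, deterministic = TRUE)
  expect_equal(unname(tr$values[2, 1]), 2)
  # seeded determinism
  ps <- mar_params(c(0.2, 0.1), matrix(c(0.5, 0.1, -0.2, 0.6), 2),
                   diag(0.04, 2))
  t1 <- simulate_mar(ps, c(0, 0), 20, seed = 9)
  t2 <- simulate_mar(ps, c(0, 0), 20, seed = 9)
  expect_identical(t1$values, t2$values)
  expect_error(simulate_mar(ps, c(0, 0), 20), "seed")
})

test_that("steady states solve the fixed-point equations", {
  expect_equal(unname(lv_steady_state(logistic_params())), 2)
  p <- lv_params(c(2, 2), diag(c(-1, -2)))
  expect_equal(unname(lv_steady_state(p)), c(2, 1))
  expect_error(lv_steady_state(lv_params(c(1, 1), matrix(1, 2, 2))),
               "rank deficient")
  expect_equal(unname(mar_steady_state(mar_params(c(3, 4), matrix(0, 2, 2)))),
               c(3, 4))
  expect_equal(unname(mar_steady_state(mar_params(c(1, 1), 0.5 * diag(2)))),
               c(2, 2))
  expect_error(mar_steady_state(mar_params(c(1, 1), diag(2))), "singular")
})

test_that("the steady-state map sends LV systems to equivalent MAR systems", {
  m <- lv_to_mar_steady_map(logistic_params())
  expect_equal(unname(m$intercepts), 1)
  expect_equal(unname(m$transition[1, 1]), 0.5)
  # zero interactions map to the identity transition
  m0 <- lv_to_mar_steady_map(lv_params(c(1, 2), matrix(0, 2, 2)))
  expect_equal(unname(m0$transition), diag(2))
  # equivalence on random nonsingular systems
  set.seed(11)
  for (i in 1:100) {
    p <- random_lv(3)
    xs_lv <- lv_steady_state(p)
    xs_mar <- mar_steady_state(lv_to_mar_steady_map(p))
    expect_equal(xs_mar, xs_lv, tolerance = 1e-10)
  }
})

test_that("Euler error shrinks about linearly in the step size", {
  p <- logistic_params()
  ode_end <- simulate_lv_ode(p, 1, sim_grid(0, 2, 1))$values[2, 1]
  err_at <- function(h) {
    abs(simulate_lv_discrete(p, 1, sim_grid(0, h, round(2 / h)))$values[round(2 / h) + 1, 1] -
          ode_end)
  }
  r1 <- err_at(0.1) / err_at(0.05)
  r2 <- err_at(0.05) / err_at(0.025)
  expect_gt(r1, 1.6); expect_lt(r1, 2.4)
  expect_gt(r2, 1.6); expect_lt(r2, 2.4)
})
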