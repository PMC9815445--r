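test_that("SSE sums squared residuals per species and over replicates", {
  pred <- trajectory(0:1, matrix(c(1, 2), 2), species = "A")
  expect_equal(sse(pred, abundance_data(0:1, matrix(c(1, 2), 2),
                                        species = "A"))$total, 0)
  expect_equal(sse(pred, abundance_data(0:1, matrix(0, 2, 1),
                                        species = "A"))$total, 5)  # 1 + 4
  # replicated observations each contribute their own residual
  obs <- abundance_data(c(0, 1, 0, 1), matrix(c(1, 2, 0, 0), 4),
                        species = "A", replicate = c("a", "a", "b", "b"))
  expect_equal(sse(pred, obs)$total, 5)
  expect_error(sse(pred, abundance_data(c(0, 0.5), matrix(1:2), species = "A")),
               "time mismatch")
})

test_that("normalized SSE is invariant to per-species rescaling", {
  pred <- trajectory(0:2, cbind(A = c(1, 2, 3), B = c(10, 20, 30)))
  obs <- abundance_data(0:2, cbind(A = c(1.1, 2.2, 2.9), B = c(11, 19, 33)))
  base <- normalized_sse(pred, obs)
  # scaling species B by 1000 on both sides leaves its contribution alone
  pred2 <- trajectory(0:2, cbind(A = c(1, 2, 3), B = 1000 * c(10, 20, 30)))
  obs2 <- abundance_data(0:2, cbind(A = c(1.1, 2.2, 2.9), B = 1000 * c(11, 19, 33)))
  expect_equal(normalized_sse(pred2, obs2)$per_species[["B"]],
               base$per_species[["B"]], tolerance = 1e-12)
  expect_equal(normalized_sse(pred, as_abundance_data(pred))$total, 0)
  zero_mean <- abundance_data(0:2, cbind(A = c(-1, 0, 1), B = c(1, 1, 1)))
  expect_error(normalized_sse(pred, zero_mean), "zero")
})

test_that("tail SSE restricts the comparison to the final grid points", {
  truth <- trajectory(1:10, matrix(1:10, 10), species = "A")
  same_tail <- trajectory(1:10, matrix(c(9, 9, 9, 9, 9, 6:10), 10),
                          species = "A")
  expect_equal(tail_sse(same_tail, truth, 5), 0)
  expect_equal(tail_sse(same_tail, truth, 10), sum((c(9, 9, 9, 9, 9) - 1:5)^2))
  expect_equal(tail_sse(same_tail, truth, 10),
               sse(same_tail, as_abundance_data(truth))$total)
  expect_error(tail_sse(trajectory(1:3, matrix(1:3)), truth, 5), "last 5")
})

test_that("sign flips count strictly opposite signs, zeros neutral", {
  tru <- rbind(c(-0.5, 0.2), c(0.1, -0.3))
  est <- rbind(c(-0.4, -0.1), c(0.2, -0.2))
  expect_equal(sign_flip_count(est, tru), 1)       # only entry (1,2) flips
  expect_equal(sign_flip_count(tru, tru), 0)
  expect_equal(sign_flip_count(-tru, tru), 4)
  z <- rbind(c(0, 0.2), c(0.1, 0))
  expect_equal(sign_flip_count(z, tru), 0)         # zeros never count
  expect_error(sign_flip_count(matrix(1, 2, 2), matrix(1, 3, 3)), "shape")
})

test_that("the series-length criterion is 5x the nonzero beta count", {
  expect_equal(min_series_length(matrix(1, 4, 4)), 80L)
  expect_equal(min_series_length(diag(c(1, 0, 0))), 5L)
  expect_equal(min_series_length(matrix(0, 3, 3)), 0L)
  expect_equal(min_series_length(make_mar_benchmark()$params), 80L)
})

test_that("the Wilcoxon comparison matches the exact enumeration", {
  # all five differences share a sign: two-sided exact p = 2 / 2^5
  res <- wilcoxon_compare(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
  expect_equal(res$p_value, 0.0625)
  expect_equal(res$n_used, 5L)
  # symmetry in the arguments
  res2 <- wilcoxon_compare(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))
  expect_equal(res2$p_value, res$p_value)
  # zero differences are dropped; all-zero is an error
  expect_error(wilcoxon_compare(1:4, 1:4), "zero")
  res3 <- wilcoxon_compare(c(1, 2, 3, 4, 5, 9), c(2, 3, 4, 5, 6, 9))
  expect_equal(res3$n_used, 5L)
})

test_that("the comparison table is complete, marked and reproducible", {
  # noise-free scenario: the data are the truth, so ALVI should score ~0
  spec <- make_lv_benchmark(1)
  spec$noise <- noise_spec(enabled = FALSE)
  truth <- scenario_truth(spec)
  scen <- list(list(name = "noise-free", data = sample_noisy(truth, 40, seed = 2),
                    truth = truth, reference = "truth", df = 12,
                    step = spec$grid$step, seed = 3))
  tab <- run_comparison(scen, methods = c("alvi-lr", "mar"),
                        config = list(mi_iters = 20))
  expect_s3_class(tab, "sse_table")
  expect_equal(tab$best_method, "alvi-lr")
  expect_lt(tab$`alvi-lr`, tab$mar)
  # reruns are identical
  tab2 <- run_comparison(scen, methods = c("alvi-lr", "mar"),
                         config = list(mi_iters = 20))
  expect_identical(as.data.frame(tab), as.data.frame(tab2))
  # unknown methods are refused
  expect_error(run_comparison(scen, methods = "magic"), "unknown method")
})

test_that("method failures are recorded as infinite SSE, never aborting", {
  # four observations cannot support df-8 smoothing nor a 4-species MAR fit,
  # but the table must still be produced
  spec <- make_lv_benchmark(1)
  truth <- scenario_truth(spec)
  tiny <- sample_noisy(truth, 5, seed = 1)
  scen <- list(list(name = "tiny", data = tiny, truth = truth,
                    reference = "truth", df = 8, step = spec$grid$step,
                    seed = 3))
  tab <- run_comparison(scen, methods = c("alvi-mi", "mar"),
                        config = list(mi_iters = 10))
  expect_true(is.infinite(tab$mar))
  expect_gt(length(attr(tab, "failures")), 0)
})

test_that("the initial-condition sweep produces the three metric tables", {
  spec <- make_lv_benchmark(5)
  spec$noise <- noise_spec(enabled = FALSE)   # keep the unit test cheap
  res <- initial_condition_sweep(spec, multipliers = c(0.1, 1.9),
                                 sampling = "noisy",
                                 methods = c("alvi-mi", "mar-log"),
                                 seed = 11, config = list(mi_iters = 30, df = 38))
  expect_named(res, c("sse", "tail_sse", "sign_flips"))
  for (m in res) expect_equal(nrow(m), 2)
  # ALVI on noise-free LV data recovers the dynamics: tiny SSE, no flips
  expect_lt(res$sse[1, "alvi-mi"], 1e-4)
  expect_equal(res$sign_flips[1, "alvi-mi"], 0)
  # sign flips are only defined in the generating parameter space
  expect_true(all(is.na(res$sign_flips[, "mar-log"])))
  # reproducibility under the same seed
  res2 <- initial_condition_sweep(spec, multipliers = c(0.1, 1.9),
                                  sampling = "noisy",
                                  methods = c("alvi-mi", "mar-log"),
                                  seed = 11, config = list(mi_iters = 30, df = 38))
  expect_identical(res, res2)
})
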