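# lvmar

Inference and comparison of species-interaction networks from community
time series under two model families:

* **Generalized Lotka–Volterra (LV)** ordinary differential equations

  dX<sub>i</sub>/dt = X<sub>i</sub> (a<sub>i</sub> + Σ<sub>j</sub> b<sub>ij</sub> X<sub>j</sub>),

  with growth rates *a* and interaction matrix *B* (row = affected
  species, column = affecting species);

* **Multivariate autoregressive MAR(1)** models

  x<sub>t+1</sub> = α + β x<sub>t</sub> + w<sub>t</sub>,  w<sub>t</sub> ~ MVN(0, δ),

  typically on log abundances (the Gompertz multispecies-competition
  reading), with process noise built into the model.

The two frameworks share their steady-state equations — with α = *a* and
β = *B* + *I* on the diagonal the MAR fixed point equals the LV interior
steady state — but differ sharply away from equilibrium.  `lvmar` lets you
fit both to the same data and measure which one captures the dynamics.

The package is aimed at ecologists, microbiome researchers and systems
biologists who have abundance time series (possibly irregular, replicated
or noisy) and want directed, signed interaction estimates rather than
correlation networks.

## What is inside

* **Simulators** — adaptive-solver LV integration, Euler-discretized LV
  with multiplicative mode-1 gamma process noise (shape *k*, scale
  1/(*k*−1)), and the stochastic MAR(1) recursion
  (`simulate_lv_ode()`, `simulate_lv_discrete()`, `simulate_mar()`).
* **ALVI** — Algebraic LV Inference: smoothing-spline slope estimation
  converts the ODE problem into per-species linear systems, solved either
  by least squares over many points (`alvi_lr()`) or exactly on *n*+1
  points (`alvi_mi()`), with a seeded Monte-Carlo/exhaustive subset search
  (`subsample_search()`) and quasi-Newton refinement (`refine_gradient()`).
* **MAR(1) estimation** — conditional least squares over consecutive pairs
  (`fit_mar()`), with the raw/log × unsmoothed/smoothed data-handling
  variants (`prepare_transform()`), free-run and one-step prediction, and
  Gaussian prediction intervals.
* **Evaluation** — SSE variants (`sse()`, `normalized_sse()`,
  `tail_sse()`), interaction sign-flip counting, the series-length rule of
  thumb (5 × nonzero entries of β), an exact-under-ties Wilcoxon
  signed-rank comparison, the scenario × method comparison table
  (`run_comparison()`) and the initial-condition sweep.
* **Synthetic benchmarks** — a 4-species LV system with one deliberately
  decoupled logistic species, a dense 4-species MAR system, noisy
  (40-of-100 random points) and replicate (15 points × 5 runs) sampling,
  and a six-regime dynamics suite (stable point, damped oscillation, limit
  cycle, sustained oscillation, two chaotic systems).

## Worked example

Fit both frameworks to a noisy 4-species LV benchmark dataset and compare:

```r
library(lvmar)

spec  <- make_lv_benchmark(seed = 1)     # 4-species LV, species 4 decoupled
lv_steady_state(spec$params)
#>        X1        X2        X3        X4
#> 0.9711538 1.3942308 1.6442308 2.0000000

tab <- run_comparison(list(benchmark_scenario("lv-noisy",  seed = 1),
                           benchmark_scenario("mar-noisy", seed = 1)),
                      config = list(mi_iters = 200, seed = 1))
tab
#>    scenario alvi-lr  alvi-mi     mar mar-log mar-smooth mar-log-smooth best_method
#> 1  lv-noisy     Inf 0.475632 3.99102 1.58641    5.07617        8.90852     alvi-mi
#> 2 mar-noisy 76.4574 6.389194 2.05444 1.28072    2.28360        2.61269     mar-log
```

Each cell is the trajectory SSE against the noise-free truth; `Inf` marks
a flagged failure (here a diverging least-squares LV fit, recorded with
its reason in `attr(tab, "failures")`).  The ranking reproduces the
expected pattern: the algebraic LV fit wins on LV-generated data, the
log-transformed MAR fit wins on MAR-generated data.

Parameter recovery is best assessed on replicated data:

```r
rep_data <- sample_replicates(spec, n_replicates = 5, seed = 1)
sm     <- fit_spline(rep_data, df = 8)
search <- subsample_search(sm, rep_data, strategy = "monte_carlo",
                           n_iter = 200, seed = 3,
                           reference = "truth", truth = scenario_truth(spec))
round(search$fits[[1]]$params$interactions, 3)
#>        X1     X2     X3     X4
#> X1 -0.144  0.011 -0.239 -0.007
#> X2 -0.211 -0.366 -0.016  0.001
#> X3 -0.009 -0.256 -0.029 -0.065
#> X4 -0.210 -0.872 -0.012 -0.224
```

The dominant (intraspecific) coefficients come back with the right sign
and order of magnitude; weak couplings can flip sign under process noise —
exactly the failure mode the sign-flip metric and the series-length
criterion (`min_series_length()`) quantify.

A thin command-line pipeline wraps the same functions:

```sh
Rscript inst/cli/lvmar generate --scenario lv-noisy --seed 7 --out out/
Rscript inst/cli/lvmar compare  --scenario lv-noisy,mar-noisy --seed 7 --out out/
```

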