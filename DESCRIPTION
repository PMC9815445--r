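Package: lvmar
Title: Lotka-Volterra and Multivariate Autoregressive Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Side-by-side inference of species interaction networks from
    community time series under two model families: generalized
    Lotka-Volterra (LV) ordinary differential equations and multivariate
    autoregressive MAR(1) models.  Provides simulators for both families,
    including Euler-discretized LV dynamics with multiplicative gamma
    process noise; algebraic LV inference (ALVI) by linear regression or
    exact matrix inversion on spline-estimated slopes, with subsample
    search and gradient refinement; conditional least-squares MAR(1)
    estimation with log/z-score/smoothing data-handling variants; and an
    evaluation harness (SSE variants, interaction-sign recovery, series
    length criterion, Wilcoxon comparison, initial-condition sweeps)
    driven by reproducible synthetic benchmark generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    MASS,
    jsonlite,
    yaml,
    optparse,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
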