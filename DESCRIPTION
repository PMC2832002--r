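Package: fiberkin
Title: Crossbridge Kinetics of Permeabilized Cardiac Muscle Fibers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward kinetic modelling and fitting tools for the actomyosin
    crossbridge cycle in permeabilized cardiac fibers. Implements a
    three-pool activation-gated scheme (non-cycling crossbridges, attached
    non-force A-M.ADP.Pi, force-bearing AM*.ADP.Pi/AM*.ADP with
    rapid-equilibrium phosphate release), closed-form and eigenvalue
    relaxation rates, ODE-simulated force transients for caged-calcium,
    caged-ATP and length-release protocols, single-exponential transient
    fitting, Hill force-pCa and phosphate-dependence (k1, k-1, K2) fitting,
    fiber stiffness regression, group statistics with Bonferroni-adjusted
    t-tests, densitometry phosphoform ratios, and a seeded synthetic-cohort
    generator with a parameter-recovery harness.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
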