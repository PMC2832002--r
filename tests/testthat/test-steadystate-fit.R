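test_that("noiseless Hill data are recovered exactly and satisfy the half-max identity", {
  ca <- 10^seq(-2, 1.5, length.out = 10)
  f <- hill_force(ca, fmax = 50.1, ec50 = 3.32, n = 2)
  fit <- fit_hill(ca, f)
  expect_equal(fit$fmax, 50.1, tolerance = 1e-6)
  expect_equal(fit$ec50, 3.32, tolerance = 1e-6)
  expect_equal(fit$n_hill, 2, tolerance = 1e-6)
  # F(ec50) = fmax / 2 identically for the fitted curve
  at_ec50 <- fit$fmax * fit$ec50^fit$n_hill /
    (fit$ec50^fit$n_hill + fit$ec50^fit$n_hill)
  expect_equal(at_ec50, fit$fmax / 2)
  # permuting point order changes nothing
  o <- sample(length(ca))
  fit2 <- fit_hill(ca[o], f[o])
  expect_equal(fit2$ec50, fit$ec50, tolerance = 1e-9)
})

test_that("non-spanning or flat force-pCa data raise identifiability errors", {
  ca <- 10^seq(-2, 1.5, length.out = 8)
  expect_error(fit_hill(ca, rep(0, 8)), "identifiable")
  expect_error(fit_hill(ca, rep(50, 8) + 1e-12), "identifiable")
  expect_error(fit_hill(ca, hill_force(ca, 50, 1e-4)), "identifiable")
  expect_error(fit_hill(c(1, 1.5, 2, 3), hill_force(c(1, 1.5, 2, 3), 50, 2)),
               "decade")
  expect_error(fit_hill(ca[1:3], hill_force(ca[1:3], 50, 3)), "4")
})

test_that("noiseless Scheme-1 Pi dependence is recovered exactly", {
  p <- perfused_params()
  pi <- c(0, 5, 10, 20, 30)
  fit <- fit_pi_dependence(pi, relaxation_rate(p, pi))
  expect_equal(fit$k1, 26.6, tolerance = 1e-6)
  expect_equal(fit$k_minus1, 42.3, tolerance = 1e-6)
  expect_equal(fit$K2, 39.4, tolerance = 1e-6)
  expect_true(fit$identified)
  # permutation invariance
  o <- c(3, 1, 5, 2, 4)
  fit2 <- fit_pi_dependence(pi[o], relaxation_rate(p, pi)[o])
  expect_equal(fit2$K2, fit$K2, tolerance = 1e-9)
  # round-trip from model_core for all groups
  for (g in c("ischemic", "reperfused")) {
    pg <- group_scheme_params(g)
    fg <- fit_pi_dependence(pi, relaxation_rate(pg, pi))
    expect_equal(c(fg$k1, fg$k_minus1, fg$K2),
                 c(pg$k1, pg$k_minus1, pg$K2), tolerance = 1e-6)
  }
})

test_that("degenerate Pi designs raise errors", {
  expect_error(fit_pi_dependence(c(0, 0, 0, 0), c(1, 2, 3, 4)), "distinct")
  expect_error(fit_pi_dependence(c(0, 5, 10, 20), rep(25, 4)), "degenerate")
})

test_that("stiffness is the slope of the force-length line", {
  dl <- c(0.05, 0.1, 0.15, 0.2) / 100
  fit <- fit_stiffness(dl, 465.8 * dl)
  expect_equal(fit$slope, 465.8, tolerance = 1e-9)
  expect_equal(fit$r2, 1)
  z <- fit_stiffness(dl, rep(0, 4))
  expect_equal(z$slope, 0, tolerance = 1e-12)
  expect_error(fit_stiffness(rep(0.001, 4), 1:4), "distinct")
  set.seed(501)
  noisy <- fit_stiffness(dl, 465.8 * dl + rnorm(4, 0, 0.05))
  expect_equal(noisy$slope, 465.8, tolerance = 0.1)
})

test_that("relative force is a percentage of the zero-Pi reference", {
  expect_equal(relative_force(26.0, 41.3), 63.0, tolerance = 0.01)
  expect_equal(relative_force(7, 7), 100)
  expect_equal(relative_force(0, 10), 0)
  expect_error(relative_force(5, 0), "> 0")
})

test_that("elliptical cross-sectional area converts diameters to mm^2", {
  expect_equal(fiber_csa(200, 100), pi * 200 * 100 / 4 * 1e-6)
  expect_error(fiber_csa(0, 10), "> 0")
})

test_that("cohort fitters support per-fiber and pooled modes", {
  cfg <- cohort_config("perfused", n_fibers = 4, pca_noise = 0, seed = 7)
  tab <- generate_force_pca_table(cfg)
  per <- fit_hill_cohort(tab, by = "fiber")
  expect_equal(nrow(per$summary), 3)
  expect_equal(per$summary$mean[per$summary$parameter == "ec50"], 3.32,
               tolerance = 1e-6)
  pooled <- fit_hill_cohort(tab, by = "group")
  expect_equal(pooled$ec50, 3.32, tolerance = 1e-6)
  kf <- generate_kf_vs_pi(cohort_config("perfused", n_fibers = 4,
                                        kf_noise_sd = 0, seed = 7))
  pg <- fit_pi_cohort(kf, by = "group")
  expect_equal(pg$K2, 39.4, tolerance = 1e-6)
})
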