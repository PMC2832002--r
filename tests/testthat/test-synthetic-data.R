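test_that("generators are deterministic under a fixed seed", {
  cfg <- cohort_config("perfused", n_fibers = 3, seed = 17)
  expect_identical(generate_force_pca_table(cfg), generate_force_pca_table(cfg))
  expect_identical(generate_kf_vs_pi(cfg), generate_kf_vs_pi(cfg))
  expect_identical(generate_densitometry(cfg, "tnt"),
                   generate_densitometry(cfg, "tnt"))
  t1 <- generate_transients(cfg, "CA_JUMP", n_traces = 2, duration = 0.4)
  t2 <- generate_transients(cfg, "CA_JUMP", n_traces = 2, duration = 0.4)
  expect_identical(t1[[1]]$force_mN_per_mm2, t2[[1]]$force_mN_per_mm2)
  # a different seed changes the draw
  cfg2 <- cohort_config("perfused", n_fibers = 3, seed = 18)
  expect_false(identical(generate_kf_vs_pi(cfg)$kf,
                         generate_kf_vs_pi(cfg2)$kf))
  # generation does not disturb the global RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generate_kf_vs_pi(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("noiseless cohorts round-trip through the fitters exactly", {
  cfg <- cohort_config("perfused", n_fibers = 3, pca_noise = 0,
                       kf_noise_sd = 0, seed = 1)
  tab <- generate_force_pca_table(cfg)
  expect_equal(tab$force,
               hill_force(tab$ca_uM, cfg$fmax, cfg$ec50, cfg$n_hill))
  hf <- fit_hill_cohort(tab, by = "fiber")
  expect_equal(hf$summary$mean[hf$summary$parameter == "ec50"], 3.32,
               tolerance = 1e-6)
  kf <- generate_kf_vs_pi(cfg)
  pf <- fit_pi_cohort(kf, by = "group")
  expect_equal(c(pf$k1, pf$k_minus1, pf$K2), c(26.6, 42.3, 39.4),
               tolerance = 1e-6)
})

test_that("noiseless CA_JUMP cohorts fit back to the model eigen rate", {
  cfg <- cohort_config("perfused", n_fibers = 1, trace_noise = 0,
                       rate_cv = 0, seed = 2)
  tr <- generate_transients(cfg, "CA_JUMP", n_traces = 1)[[1]]
  fit <- fit_single_exponential(tr)
  p_cal <- calibrate_activation(cfg$params, cfg$k_act)
  expect_equal(fit$rate, eigen_rate(p_cal, 4.5, 0), tolerance = 0.05)
  # the calibration pins the eigen rate at the published activation rate
  expect_equal(eigen_rate(p_cal, 4.5, 0), 22.0, tolerance = 1e-6)
})

test_that("ATP_JUMP synthetic traces keep the rigor start and dip", {
  cfg <- cohort_config("perfused", trace_noise = 0, seed = 3)
  tr <- generate_transients(cfg, "ATP_JUMP", n_traces = 1, duration = 0.3)[[1]]
  f <- tr$force_mN_per_mm2
  expect_lt(min(f), f[1])
  expect_gt(f[length(f)], 2 * f[1])  # active force about twice rigor force
})

test_that("stiffness quadruplets regress back to the generating slope", {
  cfg <- cohort_config("perfused", n_fibers = 6, seed = 5)
  q <- generate_stiffness_quadruplets(cfg, stiffness = 465.8)
  slopes <- vapply(split(q, q$fiber_id), function(d)
    fit_stiffness(d$delta_length_mm, d$delta_force)$slope, numeric(1))
  expect_true(all(abs(slopes - 465.8) / 465.8 < 0.1))
})

test_that("noiseless TnT phosphoform truth renormalizes to 22.2/77.8", {
  cfg <- cohort_config("perfused", dens_noise = 0, n_samples = 2, seed = 6)
  d <- generate_densitometry(cfg, "tnt")
  pct <- phosphoform_percentages(c(P1 = d$P1[1], P2 = d$P2[1]))
  expect_equal(unname(pct), c(22.2, 77.8), tolerance = 1e-3)
})

test_that("the recovery experiment reports truth vs estimate per replicate", {
  cfg <- cohort_config("perfused", n_fibers = 3, pca_noise = 0,
                       kf_noise_sd = 0, seed = 4)
  rep1 <- recovery_experiment(cfg, n_reps = 1, seed = 4)
  expect_s3_class(rep1, "recovery_report")
  expect_equal(nrow(rep1), 5)  # k1, k-1, K2, ec50, fmax
  expect_true(all(abs(rep1$estimate - rep1$truth) < 1e-5))
  summ <- summarize_recovery(rep1)
  expect_true(all(abs(summ$bias) < 1e-5, na.rm = TRUE))

  two <- recovery_experiment(list(cfg, cohort_config("ischemic",
                                                     n_fibers = 2, seed = 9)),
                             n_reps = 3, seed = 1)
  expect_equal(nrow(two), 3 * 2 * 5)  # reps x groups x parameters
})
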