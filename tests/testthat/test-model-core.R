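test_that("relaxation rate follows the Scheme-1 closed form", {
  p <- perfused_params()
  # at zero Pi the observed rate is exactly k1
  expect_identical(relaxation_rate(p, 0), p$k1)
  # Pi = K2 halves the saturating term: 26.6 + 42.3/2
  expect_equal(relaxation_rate(p, 39.4), 47.75)
  # approaches k1 + k-1 from below at large Pi
  pi_isch <- ischemic_params()
  expect_lt(relaxation_rate(pi_isch, 1e6), 18.9 + 30.7)
  expect_equal(relaxation_rate(pi_isch, 1e6), 49.6, tolerance = 1e-3)
  # strictly increasing in Pi
  kf <- relaxation_rate(p, seq(0, 30, by = 1))
  expect_true(all(diff(kf) > 0))
  expect_error(relaxation_rate(p, -1), "pi_mM")
})

test_that("steady state conserves occupancy and closes the gate at low Ca2+", {
  p <- perfused_params()
  ss9 <- steady_state(p, pCa = 9)
  expect_lt(ss9$force, 1e-3 * p$f_scale)
  set.seed(301)
  for (i in 1:10) {
    pr <- random_valid_params()
    ss <- steady_state(pr, pCa = stats::runif(1, 4, 9),
                       pi_mM = stats::runif(1, 0, 30))
    expect_equal(sum(ss$occupancy), 1, tolerance = 1e-9)
    expect_true(all(ss$occupancy >= 0))
    expect_equal(ss$force,
                 pr$f_scale * (ss$occupancy[["AMstar_ADP_Pi"]] +
                               ss$occupancy[["AMstar_ADP"]]))
  }
})

test_that("steady force decreases with Pi and increases with Ca2+", {
  p <- perfused_params()
  f_pi <- vapply(c(0, 5, 10, 20, 30), function(x)
    steady_state(p, 4.5, x)$force, numeric(1))
  expect_true(all(diff(f_pi) < 0))
  expect_lt(steady_state(p, 4.5, 30)$force, steady_state(p, 4.5, 0)$force)
  f_ca <- vapply(c(8, 6.5, 6, 5.5, 5, 4.5), function(pca)
    steady_state(p, pca, 0)$force, numeric(1))
  expect_true(all(diff(f_ca) > 0))
})

test_that("group parameter sets reproduce the published maximal forces", {
  for (g in c("perfused", "ischemic", "reperfused")) {
    p <- group_scheme_params(g)
    expect_equal(steady_state(p, 4.5, 0)$force, group_truth(g)$fmax,
                 tolerance = 1e-9)
  }
})

test_that("eigen rate is the oracle for the closed-form relaxation rate", {
  for (g in c("perfused", "ischemic", "reperfused")) {
    p <- group_scheme_params(g)
    for (pi in c(0, 5, 10, 20, 30)) {
      expect_equal(eigen_rate(p, 4.5, pi), relaxation_rate(p, pi),
                   tolerance = 0.05)
    }
  }
  # one-way limit: no reverse flux, no recycling -> slowest mode is k1 itself
  p1 <- scheme_params(k1 = 12, k_minus1 = 0, K2 = 10, g_off = 0)
  expect_equal(eigen_rate(p1, 4.5, 0), 12, tolerance = 1e-9)
  set.seed(302)
  for (i in 1:10) expect_gt(eigen_rate(random_valid_params(), 4.5, 0), 0)
})

test_that("CA_JUMP transients relax to steady state at the eigen rate", {
  p <- perfused_params()
  tr <- simulate_transient(p, protocol("CA_JUMP"))
  ss <- steady_state(p, 4.5, 0)$force
  expect_equal(tr$force_mN_per_mm2[nrow(tr)], ss, tolerance = 0.01)
  fit <- fit_single_exponential(tr)
  expect_equal(fit$rate, eigen_rate(p, 4.5, 0), tolerance = 0.05)
})

test_that("ATP_JUMP traces start at rigor force and dip before rising", {
  p <- perfused_params()
  tr <- simulate_transient(p, protocol("ATP_JUMP"))
  f <- tr$force_mN_per_mm2
  ss <- steady_state(p, 4.5, 0)
  occ_f <- ss$occupancy[["AMstar_ADP_Pi"]] + ss$occupancy[["AMstar_ADP"]]
  expect_equal(f[1], p$f_scale * occ_f / 3, tolerance = 1e-6)
  expect_lt(min(f), f[1])          # the post-photolysis dip
  expect_lt(which.min(f), 0.1 * length(f))  # brief: early in the record
  expect_gt(f[length(f)], f[1])    # net force development
})

test_that("protocol and parameter validation reject bad inputs", {
  expect_error(protocol("CA_JUMP", pCa = 3), "pCa")
  expect_error(protocol("CA_JUMP", duration = 0), "duration")
  expect_error(scheme_params(k1 = -1, k_minus1 = 1, K2 = 1), "rates")
  expect_error(scheme_params(k1 = 1, k_minus1 = 1, K2 = 0), "K2")
})
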