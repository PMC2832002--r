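test_that("noiseless mono-exponential traces are recovered to near machine precision", {
  for (true_rate in c(5, 22, 58.5)) {
    tr <- exp_rise_trace(rate = true_rate, f_inf = 50)
    fit <- fit_single_exponential(tr)
    expect_equal(fit$rate, true_rate, tolerance = 1e-6)
    expect_equal(fit$f_inf, 50, tolerance = 1e-6)
    expect_equal(fit$f0, 0, tolerance = 1e-4)
    expect_gt(fit$r2, 1 - 1e-10)
  }
})

test_that("degenerate and undersampled traces raise errors", {
  flat <- force_trace(seq(0, 0.5, 0.001), rep(10, 501))
  expect_error(fit_single_exponential(flat, c(0, 0.5)), "degenerate")
  short <- exp_rise_trace()
  expect_error(fit_single_exponential(short, c(0, 0.005)), "10 samples")
  expect_error(fit_single_exponential(short, c(0.5, 0)), "window")
})

test_that("rate recovery at 2% trace noise is within 5% (seeded)", {
  set.seed(401)
  rates <- replicate(20, {
    tr <- exp_rise_trace(rate = 22, f_inf = 50)
    noisy <- force_trace(tr$time_s,
                         tr$force_mN_per_mm2 + rnorm(nrow(tr), 0, 0.02 * 50),
                         protocol_kind = "CA_JUMP")
    fit_single_exponential(noisy)$rate
  })
  expect_true(all(abs(rates - 22) / 22 < 0.05))
  # recovery bias under the stated conditions is < 2%
  expect_lt(abs(mean(rates) - 22) / 22, 0.02)
})

test_that("fit windows are protocol-aware", {
  rising <- exp_rise_trace(kind = "CA_JUMP")
  expect_equal(detect_fit_window(rising),
               range(rising$time_s), tolerance = 1e-12)

  # constructed caged-ATP trace with its dip at t = 0.01 s
  t <- seq(0, 0.5, by = 0.001)
  dip <- 17 - 5 * t / 0.01
  dip[t > 0.01] <- 12 + 38 * (1 - exp(-25 * (t[t > 0.01] - 0.01)))
  atp <- force_trace(t, dip, protocol_kind = "ATP_JUMP")
  w <- detect_fit_window(atp)
  expect_equal(w[1], 0.01)
  expect_equal(w[2], 0.5)

  falling <- force_trace(t, 50 * exp(-3 * t), protocol_kind = "ATP_JUMP")
  expect_error(detect_fit_window(falling), "minimum at final sample")
  tiny <- force_trace(1:10 / 100, 1:10)
  expect_error(detect_fit_window(tiny), "50 samples")
})
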