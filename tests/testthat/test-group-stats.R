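test_that("group summaries report mean, SEM and n", {
  s <- group_summary(c(1, 2, 3), "demo")
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 1 / sqrt(3), tolerance = 1e-9)  # sd([1,2,3]) = 1
  expect_equal(s$n, 3)
  one <- group_summary(4.2)
  expect_equal(one$mean, 4.2)
  expect_equal(one$sem, 0)
  expect_equal(group_summary(rep(7, 5))$sem, 0)
  expect_error(group_summary(numeric(0)), "one value")
})

test_that("pairwise comparisons use Bonferroni-adjusted significance", {
  a <- c(1, 2, 3); b <- c(101, 102, 103)
  cr <- compare_groups(a, b, m_comparisons = 3)
  expect_equal(cr$adjusted_alpha, 0.05 / 3)
  expect_lt(cr$p_value, 1e-4)
  expect_true(cr$significant)
  # identical samples: no evidence of difference
  same <- compare_groups(a, a, m_comparisons = 3)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)
  # Bonferroni identity for several family sizes
  for (m in 1:6)
    expect_equal(compare_groups(a, b, m)$adjusted_alpha * m, 0.05)
  expect_error(compare_groups(1, b), "n >= 2")
  # Welch and Student agree for equal-variance balanced data
  w <- compare_groups(a, b, welch = TRUE)
  expect_equal(w$p_value, cr$p_value, tolerance = 1e-6)
})

test_that("phosphoform percentages partition the total signal", {
  p <- phosphoform_percentages(c(P1 = 221, P2 = 779))
  expect_equal(unname(p), c(22.1, 77.9))
  expect_equal(sum(p), 100, tolerance = 1e-9)
  expect_equal(unname(phosphoform_percentages(c(a = 5, b = 5))), c(50, 50))
  expect_equal(unname(phosphoform_percentages(c(P1 = 0, P2 = 3))), c(0, 100))
  expect_error(phosphoform_percentages(c(0, 0)), "zero")
  expect_error(phosphoform_percentages(c(-1, 2)), ">= 0")
  set.seed(601)
  for (i in 1:5) {
    s <- runif(3, 0, 100)
    expect_equal(sum(phosphoform_percentages(s)), 100, tolerance = 1e-9)
  }
})

test_that("relative phosphorylation is scaled to the reference and scale-invariant", {
  rec <- data.frame(sample_id = paste0("s", 1:6),
                    group = rep(c("perfused", "ischemic"), each = 3),
                    phospho = c(50, 55, 45, 33, 36, 30),
                    total = c(100, 110, 90, 100, 110, 90))
  out <- relative_phosphorylation(rec, "perfused")
  expect_equal(mean(out$percent_of_reference[out$group == "perfused"]), 100)
  # doubling all intensities changes nothing
  rec2 <- rec; rec2$phospho <- rec2$phospho * 2; rec2$total <- rec2$total * 2
  out2 <- relative_phosphorylation(rec2, "perfused")
  expect_equal(out2$percent_of_reference, out$percent_of_reference)
  expect_error(relative_phosphorylation(transform(rec, total = 0), "perfused"),
               "total")
  expect_error(relative_phosphorylation(rec, "nope"), "reference")
})

test_that("a synthetic ischemic cohort recovers the relative Ser23/24 decline", {
  cfg_p <- cohort_config("perfused", n_samples = 40, seed = 11)
  cfg_i <- cohort_config("ischemic", n_samples = 40, seed = 12)
  rec <- rbind(generate_densitometry(cfg_p, "tni"),
               generate_densitometry(cfg_i, "tni"))
  out <- relative_phosphorylation(rec, "perfused")
  m_isch <- mean(out$percent_of_reference[out$group == "ischemic"])
  # generated at 0.659x the reference ratio
  expect_equal(m_isch, 65.9, tolerance = 0.1 * 65.9)
})
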