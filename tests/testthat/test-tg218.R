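test_that("action_interval combines random and systematic components", {
  expect_equal(action_interval(tg218_params(100, 100, 2, beta = 6))[["lower"]], 94)
  expect_equal(action_interval(tg218_params(100, 98, 0, beta = 6))[["lower"]], 94)
  ai <- action_interval(tg218_params(100, 99, 1.5, beta = 4))
  expect_equal(100 - ai[["lower"]], 2 * sqrt(2.25 + 1))   # A = 3.6056
  expect_error(tg218_params(100, 99, 1, beta = 0), "parameter error")
})

test_that("beta_half_from_q and q_from_beta_half are exact inverses", {
  # q <= 0.5 keeps beta/2 non-negative (the formalism's domain)
  qs <- c(0.0005, 0.0014, 0.0027, 0.02, 0.05, 0.1, 0.2, 0.5)
  for (s in c("one_sided", "two_sided")) {
    b <- beta_half_from_q(qs, s)
    expect_equal(q_from_beta_half(b, s), qs, tolerance = 1e-10)
  }
  bs <- c(0.5, 1, 2, 3, 4)   # b = 0 maps to the open-interval endpoint
  for (s in c("one_sided", "two_sided"))
    expect_equal(beta_half_from_q(q_from_beta_half(bs, s), s),
                 bs, tolerance = 1e-10)
  expect_equal(beta_half_from_q(0.5, "one_sided"), 0)
  expect_equal(q_from_beta_half(0, "two_sided"), 1)
  expect_error(beta_half_from_q(1.2), "parameter error")
})

test_that("expected_fail_rate implements both sidednesses", {
  expect_equal(round(expected_fail_rate(1.75, 2.41, 4.5, "two_sided")), 13)
  expect_equal(expected_fail_rate(95, 2, 95, "one_sided"), 50)
  expect_lt(expected_fail_rate(0, 1, 1e6, "two_sided"), 1e-10)
  # degenerate sd: exact 0 or 100
  expect_equal(expected_fail_rate(96, 0, 95, "one_sided"), 0)
  expect_equal(expected_fail_rate(94, 0, 95, "one_sided"), 100)
  expect_equal(expected_fail_rate(-5, 0, 4.5, "two_sided"), 100)
})

test_that("binomial_se follows 100*sqrt(p(1-p)/n)", {
  expect_equal(binomial_se(0.5, 100), 5)
  expect_equal(binomial_se(0, 50), 0)
  expect_equal(binomial_se(1, 50), 0)
  expect_equal(round(binomial_se(0.13, 100), 2), 3.36)
})

test_that("clipped-GPR sampler hits the requested moments", {
  set.seed(77)
  x <- sample_clipped_gpr(2e5, 98, 1.4)
  expect_true(all(x <= 100))
  expect_lt(abs(mean(x) - 98), 0.02)
  expect_lt(abs(sd(x) - 1.4), 0.02)
  expect_error(sample_clipped_gpr(10, 100.5, 1),
               "parameter error")
})

test_that("truncation correction is ~1 far from the bound and > 1 near it", {
  far <- truncation_beta_correction(80, 2, 0.1, reps = 5e4, seed = 3)
  expect_lt(abs(far - 1), 0.05)
  near <- truncation_beta_correction(98, 1.4, 0.1, reps = 5e4, seed = 3)
  expect_gt(near, 1)
  expect_error(truncation_beta_correction(98, 1.4, 0.1, reps = 100),
               "reps")
})

test_that("truncation correction grows as the mean approaches the bound", {
  f <- vapply(c(90, 96, 99),
              function(m) truncation_beta_correction(m, 1.4, 0.1,
                                                     reps = 5e4, seed = 9), 0)
  expect_true(all(diff(f) > -0.01))   # non-decreasing up to simulation error
})

test_that("tg218_table reports every metric with coherent columns", {
  co <- sample_result_cohort(cohort_sim_config("SMCcbm"), seed = 13)
  tab <- tg218_table(co, q = c(0.05, 0.1))
  expect_equal(nrow(tab), 2 * 5)
  expect_true(all(tab$beta_half > 0))
  expect_true(all(tab$expected_fail_pct >= 0 & tab$expected_fail_pct <= 100))
  expect_true(all(tab$binomial_se_pct >= 0 & tab$binomial_se_pct <= 5))
  # two-sided levels are wider multiples than one-sided for the same q
  for (q in unique(tab$q))
    expect_gt(tab$beta_half[tab$metric == "dd" & tab$q == q][1],
              max(tab$beta_half[tab$metric == "gpr" & tab$q == q]))
})
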