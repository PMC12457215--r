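test_that("qa_percentile uses the linear-interpolation convention", {
  expect_equal(qa_percentile(1:5, 0.5), 3)
  expect_equal(qa_percentile(rep(7.3, 9), c(0, 0.4, 1)), rep(7.3, 3))
  expect_equal(qa_percentile(c(10, 20, 30, 40), 0.25), 17.5)
  expect_error(qa_percentile(numeric(0), 0.5), "empty-statistics")
})

test_that("gpr_action_level rounds the q-quantile to a multiple of 5", {
  al <- gpr_action_level(rep(97.3, 10), 0.1)
  expect_equal(al$threshold, 95)        # 97.3 is nearer 95 than 100
  expect_equal(al$sidedness, "one_sided_lower")

  gprs <- c(88, 90, 92, 93, 94, 95, 96, 97, 98, 99)
  al1 <- gpr_action_level(gprs, 0.2, granularity = 1)
  expect_equal(al1$threshold, 92)       # quantile 91.6 -> nearest integer
  expect_equal(al1$quantile_raw, 91.6)

  expect_lte(gpr_action_level(rep(100, 5), 0.1)$threshold, 100)
  expect_error(gpr_action_level(gprs, 0), "parameter error")
})

test_that("dd_action_level supports both rounding conventions", {
  dds <- c(1, -1, 2, -2, 3, -3, 4, -4, 5, -5)
  near <- dd_action_level(dds, 0.2)
  expect_equal(near$quantile_raw, 4.2)
  expect_equal(near$threshold, 4.0)     # nearest multiple of 0.5
  up <- dd_action_level(dds, 0.2, convention = "outward")
  expect_equal(up$threshold, 4.5)       # round-up convention

  expect_equal(dd_action_level(rep(0, 8), 0.1)$threshold, 0.5)
})

test_that("dd_action_level threshold is non-increasing in q", {
  set.seed(8)
  for (rep in 1:5) {
    dds <- rnorm(60, 0.5, 2)
    thr <- vapply(c(0.02, 0.05, 0.1, 0.2, 0.4),
                  function(q) dd_action_level(dds, q)$threshold, 0)
    expect_true(all(diff(thr) <= 1e-12))
  }
})

test_that("observed_failure_rate counts strict failures", {
  co <- data.frame(plan_id = 1:3, delta_d = c(-2, 0.5, 1.6),
                   gpr_3_3 = c(89, 94, 96))
  al_g <- fixed_action_level("gpr", 95, criterion = "gpr_3_3")
  expect_equal(observed_failure_rate(co, al_g), 200 / 3)
  al_d <- fixed_action_level("dd", 1.5)
  expect_equal(observed_failure_rate(co, al_d), 200 / 3)
  expect_equal(observed_failure_rate(co, fixed_action_level("gpr", 80,
                                                            criterion = "gpr_3_3")), 0)
  expect_error(observed_failure_rate(co, fixed_action_level("gpr", 90,
                                                            criterion = "gpr_2_1")),
               "data error")
})

test_that("combined_table reproduces the 2x2 bookkeeping", {
  # 100 plans: 11 gamma failures, 10 dd failures, 3 failing both
  gpr <- rep(95, 100); gpr[1:11] <- 85
  dd <- rep(0, 100); dd[c(1:3, 12:18)] <- 6
  co <- data.frame(plan_id = 1:100, delta_d = dd, gpr_3_3 = gpr)
  ct <- combined_table(co,
                       fixed_action_level("gpr", 90, criterion = "gpr_3_3"),
                       fixed_action_level("dd", 4.5))
  expect_equal(ct$passed_both, 82)
  expect_equal(ct$failed_both, 3)
  expect_equal(ct$failed_gamma, 11)
  expect_equal(ct$failed_dd, 10)
  expect_identity_holds(ct)

  none <- combined_table(data.frame(plan_id = 1, delta_d = 0, gpr_3_3 = 100),
                         fixed_action_level("gpr", 90, criterion = "gpr_3_3"),
                         fixed_action_level("dd", 1))
  expect_equal(unlist(none[c("passed_both", "failed_both", "failed_gamma",
                             "failed_dd")]),
               c(passed_both = 100, failed_both = 0, failed_gamma = 0,
                 failed_dd = 0))
})

test_that("combined-table identity and joint bound hold on random cohorts", {
  set.seed(12)
  for (rep in 1:6) {
    n <- 50
    co <- data.frame(plan_id = seq_len(n),
                     delta_d = rnorm(n, 0, 3),
                     gpr_3_3 = pmin(100, rnorm(n, 93, 5)))
    ct <- combined_table(co,
                         fixed_action_level("gpr", 90, criterion = "gpr_3_3"),
                         fixed_action_level("dd", 3))
    expect_identity_holds(ct)
    expect_lte(ct$failed_both, min(ct$failed_gamma, ct$failed_dd))
  }
})

test_that("unrounded percentile levels hit the target rate within 1/n", {
  for (fl in c("M3D", "SMCgen", "SMCcbm")) {
    co <- sample_result_cohort(cohort_sim_config(fl), seed = 31)
    n <- nrow(co)
    for (q in c(0.02, 0.05, 0.1, 0.2)) {
      alg <- gpr_action_level(co$gpr_2_1, q, criterion = "gpr_2_1")
      expect_lte(abs(observed_failure_rate(co, alg, use_raw = TRUE) / 100 - q),
                 1 / n + 1e-12)
      ald <- dd_action_level(co$delta_d, q)
      expect_lte(abs(observed_failure_rate(co, ald, use_raw = TRUE) / 100 - q),
                 1 / n + 1e-12)
    }
  }
})

test_that("action_level_table covers every metric at every q", {
  co <- sample_result_cohort(cohort_sim_config("SMCgen"), seed = 5)
  tab <- action_level_table(co)
  expect_equal(nrow(tab), 4 * 5)          # 4 q values x (4 GPR + dd)
  expect_true(all(tab$threshold[tab$metric == "gpr"] <= 100))
  expect_true(all(tab$threshold[tab$metric == "dd"] > 0))
})
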