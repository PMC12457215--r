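test_that("reference plan is prescription in the target with falloff outside", {
  cfg <- small_plan_cfg()
  p <- make_reference_plan(cfg)
  expect_equal(max_dose(p$grid), cfg$prescription)
  inside <- p$grid$values[p$target$values]
  expect_lt(abs(mean(inside) / cfg$prescription - 1), 0.01)
  expect_true(p$target$values[which.max(p$grid$values)])
  expect_identical(make_reference_plan(cfg)$grid$values, p$grid$values)
  expect_error(plan_sim_config(shape = c(10, 10, 10), radii = c(50, 50, 50)),
               "geometry error")
})

test_that("perturb_plan reduces to identity and exact scaling", {
  cfg0 <- small_plan_cfg(sys_mean = 0, sys_sd = 0, local_amp = 0)
  p <- make_reference_plan(cfg0)
  pp <- perturb_plan(p$grid, cfg0, seed = 4)
  expect_equal(pp$grid$values, p$grid$values, tolerance = 1e-12)
  expect_equal(mean_target_dose_diff(p$grid, pp$grid, p$target), 0)

  cfg2 <- small_plan_cfg(sys_mean = 2, sys_sd = 0, local_amp = 0)
  pp2 <- perturb_plan(p$grid, cfg2, seed = 4)
  expect_equal(pp2$sys_error, 2)
  expect_equal(mean_target_dose_diff(p$grid, pp2$grid, p$target), 2,
               tolerance = 1e-9)
})

test_that("voxel noise is calibrated to the requested relative SD", {
  cfg <- small_plan_cfg(sys_mean = 0, sys_sd = 0, local_amp = 0,
                        mc_noise_rel_sd = 0.5)
  p <- make_reference_plan(cfg)
  pp <- perturb_plan(p$grid, cfg, seed = 6)
  m70 <- fractional_mask(p$grid, 0.7)$values
  rel_sd <- 100 * sd((pp$grid$values[m70] - p$grid$values[m70]) /
                     p$grid$values[m70])
  expect_lt(abs(rel_sd / 0.5 - 1), 0.1)    # within 10% relative
})

test_that("rigid shifts move the dose field as configured", {
  cfg <- small_plan_cfg(sys_mean = 0, sys_sd = 0, local_amp = 0,
                        shift = c(2.5, 0, 0))
  p <- make_reference_plan(cfg)
  pp <- perturb_plan(p$grid, cfg, seed = 2)
  # a shift of exactly one voxel: interior planes coincide with the neighbor
  expect_equal(pp$grid$values[5:30, , ], p$grid$values[4:29, , ],
               tolerance = 1e-9)
})

test_that("result-level cohort has the stated structure and moments", {
  cfg <- cohort_sim_config("M3D")
  co <- sample_result_cohort(cfg, seed = 1)
  expect_equal(nrow(co), 100)
  expect_equal(length(unique(co$case_class)), 20)
  expect_equal(unname(table(co$case_class)[1]), 5)

  big <- sample_result_cohort(cohort_sim_config("M3D", n_case_classes = 2000),
                              seed = 2)
  expect_lt(abs(mean(big$delta_d) - 1.75), 3 * 2.41 / sqrt(10000))

  gcols <- c("gpr_5_3", "gpr_3_3", "gpr_2_2", "gpr_2_1")
  g <- as.matrix(co[gcols])
  expect_true(all(g[, 1] >= g[, 2] & g[, 2] >= g[, 3] & g[, 3] >= g[, 4]))
  expect_true(all(g <= 100 & g >= 0))
})

test_that("voxel cohort recovers the injected systematic parameters", {
  cfg <- small_plan_cfg(sys_mean = 1.75, sys_sd = 2.41)
  co <- simulate_voxel_cohort(60, cfg, seed = 17)
  # dD per plan tracks the drawn systematic error up to the local field,
  # whose target-mean contribution is of order its 1% amplitude
  expect_lt(sd(co$delta_d - co$sys_error), 1.5)
  expect_lt(abs(mean(co$delta_d) - 1.75), 3 * 2.41 / sqrt(60) + 0.3)
})

test_that("stronger perturbations never raise the median GPR", {
  amps <- c(0, 2.5, 5)
  wins <- 0
  for (seed in 1:3) {
    med <- vapply(amps, function(a) {
      cfg <- small_plan_cfg(sys_mean = 1, sys_sd = 0, local_amp = a)
      p <- make_reference_plan(cfg)
      g <- vapply(1:3, function(i)
        gamma_pass_rate(gamma_map(p$grid,
                                  perturb_plan(p$grid, cfg, seed = 100 * seed + i)$grid,
                                  gamma_criterion(2, 2))), 0)
      median(g)
    }, 0)
    if (all(diff(med) <= 1e-9)) wins <- wins + 1
  }
  expect_gte(wins, 2)    # 3-seed majority
})
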