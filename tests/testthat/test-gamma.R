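test_that("identical grids give gamma zero everywhere and GPR 100", {
  pr <- random_pair(seed = 3)
  gm <- gamma_map(pr$ref, pr$ref, gamma_criterion(3, 3))
  expect_equal(max(gm$values[gm$evaluated_mask]), 0)
  expect_equal(gamma_pass_rate(gm), 100)
})

test_that("uniform dose offset has the closed-form gamma", {
  u <- uniform_grid(50, c(8, 8, 8))
  off <- dose_grid(u$values + 0.04 * 50, u$origin, u$spacing)
  g33 <- gamma_map(u, off, gamma_criterion(3, 3))
  expect_equal(unique(round(g33$values[g33$evaluated_mask], 10)), 4 / 3)
  expect_equal(gamma_pass_rate(g33), 0)

  g53 <- gamma_map(u, off, gamma_criterion(5, 3))
  expect_equal(unique(round(g53$values[g53$evaluated_mask], 10)), 0.8)
  expect_equal(gamma_pass_rate(g53), 100)
})

test_that("two-voxel 1D case matches hand enumeration", {
  ref <- dose_grid(array(c(1, 1), c(2, 1, 1)), spacing = c(3, 1, 1))
  ev <- dose_grid(array(c(1, 1.06), c(2, 1, 1)), spacing = c(3, 1, 1))
  gm <- brute_force_gamma(ref, ev, gamma_criterion(3, 3, low_dose_threshold = 0))
  # voxel 2: own position gives 0.06/0.03 = 2; neighbor at 3 mm gives sqrt(1)
  expect_equal(gm$values[2, 1, 1], 1)
  expect_equal(gm$values[1, 1, 1], 0)
})

test_that("engine without interpolation equals the brute-force oracle", {
  for (seed in 1:12) {
    set.seed(seed)
    shp <- sample(5:12, 3, replace = TRUE)
    sp <- runif(3, 2, 3.5)
    pr <- random_pair(shp, sp, rel_sd = 0.03, seed = seed + 100)
    crit <- gamma_criterion(3, 3)
    gv <- gamma_map(pr$ref, pr$ev, crit, interp = FALSE)
    gb <- brute_force_gamma(pr$ref, pr$ev, crit)
    expect_equal(gv$values, gb$values, tolerance = 1e-12)
    gi <- gamma_map(pr$ref, pr$ev, crit, interp = TRUE)
    expect_true(all(gi$values <= gb$values + 1e-10, na.rm = TRUE))
  }
})

test_that("oracle handles differing eval geometry", {
  pr <- random_pair(c(8, 8, 8), c(3, 3, 3), seed = 7)
  ev2 <- resample_onto(pr$ev, origin = c(1.2, 0.8, 1.5),
                       spacing = c(2.4, 2.6, 2.2), dim = c(9, 9, 9))$grid
  crit <- gamma_criterion(3, 3)
  expect_equal(gamma_map(pr$ref, ev2, crit, interp = FALSE)$values,
               brute_force_gamma(pr$ref, ev2, crit)$values, tolerance = 1e-12)
})

test_that("gamma is symmetric in the sign of a uniform dose error", {
  u <- uniform_grid(60, c(7, 7, 7))
  up <- dose_grid(u$values * 1.025, u$origin, u$spacing)
  dn <- dose_grid(u$values * 0.975, u$origin, u$spacing)
  crit <- gamma_criterion(2, 2)
  gu <- gamma_map(u, up, crit)
  gd <- gamma_map(u, dn, crit)
  expect_equal(gu$values, gd$values, tolerance = 1e-9)
})

test_that("gamma_pass_rate counts strictly below one", {
  u <- uniform_grid(1, c(4, 1, 1))
  gm <- gamma_map(u, u, gamma_criterion(3, 3))
  gm$values[] <- c(0.2, 0.9, 1.0, 1.3)
  expect_equal(gamma_pass_rate(gm), 50)

  # uniform +2% offset at (2,2): gamma = 1 exactly, strict inequality fails
  off <- dose_grid(uniform_grid(50)$values * 1.02, spacing = rep(2.5, 3))
  expect_equal(gamma_pass_rate(gamma_map(uniform_grid(50), off,
                                         gamma_criterion(2, 2))), 0)
})

test_that("the low-dose threshold removes voxels from both sides of the rate", {
  vals <- array(1, c(6, 6, 6))
  vals[4:6, , ] <- 100                       # half the grid at 1% of max
  ref <- dose_grid(vals, spacing = c(2.5, 2.5, 2.5))
  ev <- dose_grid(vals * 1.04, ref$origin, ref$spacing)
  gm <- gamma_map(ref, ev, gamma_criterion(3, 3))
  expect_equal(sum(gm$evaluated_mask), sum(vals == 100))
  expect_true(all(is.na(gm$values[vals == 1])))
  # included voxels all fail (uniform 4% > 3%), excluded ones don't dilute it
  expect_equal(gamma_pass_rate(gm), 0)
})

test_that("gamma errors on degenerate inputs", {
  u <- uniform_grid(1)
  expect_error(gamma_map(dose_grid(array(0, c(3, 3, 3))), u,
                         gamma_criterion(3, 3)), "empty-grid")
  far <- dose_grid(array(1, c(3, 3, 3)), origin = c(1e5, 1e5, 1e5))
  expect_error(gamma_map(u, far, gamma_criterion(3, 3)), "geometry error")
  expect_error(brute_force_gamma(dose_grid(array(1, c(30, 30, 30))), u,
                                 gamma_criterion(3, 3)), "size error")
})

test_that("GPR is monotone across the four standard criteria", {
  cfg <- small_plan_cfg(sys_mean = 3, sys_sd = 0, local_amp = 2)
  p <- make_reference_plan(cfg)
  ev <- perturb_plan(p$grid, cfg, seed = 21)$grid
  gprs <- vapply(default_criteria(),
                 function(cr) gamma_pass_rate(gamma_map(p$grid, ev, cr)), 0)
  expect_true(all(diff(gprs) <= 1e-9))   # (5,3) >= (3,3) >= (2,2) >= (2,1)
})
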