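test_that("dose_grid validates its invariants", {
  expect_error(dose_grid(array(-1, c(2, 2, 2))), "non-negative")
  expect_error(dose_grid(array(NA_real_, c(2, 2, 2))), "finite")
  expect_error(dose_grid(array(1, c(2, 2, 2)), spacing = c(1, 0, 1)), "positive")
  expect_error(dose_grid(matrix(1, 2, 2)), "3D")
  g <- dose_grid(array(1:8, c(2, 2, 2)), origin = c(1, 2, 3), spacing = c(1, 2, 3))
  expect_s3_class(g, "dose_grid")
  ax <- grid_axes(g)
  expect_equal(ax[[3]], c(3, 6))
})

test_that("fractional_mask thresholds at a fraction of the maximum", {
  u <- uniform_grid(10)
  expect_true(all(fractional_mask(u, 0.05)$values))

  g <- dose_grid(array(c(1, 3, 100, 1), c(4, 1, 1)))
  m <- fractional_mask(g, 0.05)             # cut at 5 Gy
  expect_equal(which(m$values), 3L)

  g2 <- dose_grid(array(c(60, 80), c(2, 1, 1)))
  m2 <- fractional_mask(g2, 0.70)           # cut at 56 Gy: both pass
  expect_true(all(m2$values))

  expect_error(fractional_mask(dose_grid(array(0, c(2, 2, 2))), 0.05),
               "empty-grid")
  expect_error(fractional_mask(u, 0), "fraction")
})

test_that("fractional_mask is monotone in the fraction", {
  set.seed(4)
  g <- dose_grid(array(runif(5^3, 0, 70), c(5, 5, 5)))
  prev <- fractional_mask(g, 0.05)$values
  for (f in c(0.2, 0.5, 0.8, 0.95)) {
    cur <- fractional_mask(g, f)$values
    expect_true(all(prev | !cur))   # raising the fraction never adds voxels
    prev <- cur
  }
})

test_that("resample_onto reproduces identity and constants", {
  pr <- random_pair(seed = 2)
  rs <- resample_onto(pr$ref, target = pr$ref)
  expect_equal(rs$grid$values, pr$ref$values, tolerance = 1e-12)
  expect_false(any(rs$out_of_support$values))

  cst <- uniform_grid(7, c(8, 8, 8), spacing = 2)
  rs2 <- resample_onto(cst, origin = c(1.3, 2.1, 0.7), spacing = c(1.1, 0.9, 1.7),
                       dim = c(5, 5, 5))
  expect_equal(rs2$grid$values, array(7, c(5, 5, 5)), tolerance = 1e-12)
})

test_that("trilinear resampling is exact for linear fields", {
  # 1D ramp d(x) = x sampled at voxel-center midpoints
  n <- 11
  ramp <- dose_grid(array(rep(0:(n - 1), 4), c(n, 2, 2)),
                    origin = c(0, 0, 0), spacing = c(1, 1, 1))
  rs <- resample_onto(ramp, origin = c(0.5, 0, 0), spacing = c(1, 1, 1),
                      dim = c(n - 1, 2, 2))
  expect_equal(as.vector(rs$grid$values[, 1, 1]), 0:(n - 2) + 0.5)

  # general affine field reproduced at interior points
  g <- dose_grid(outer(outer(seq(10, 20, length = 9), seq(0, 4, length = 9), "+"),
                       seq(0, 8, length = 9), "+"),
                 spacing = c(2, 2, 2))
  rs2 <- resample_onto(g, origin = c(1, 1, 1), spacing = c(2.7, 1.9, 2.3),
                       dim = c(5, 5, 5))
  ax <- grid_axes(rs2$grid)
  expected <- outer(outer(10 + ax[[1]] / 16 * 10, ax[[2]] / 16 * 4, "+"),
                    ax[[3]] / 16 * 8, "+")
  expect_equal(rs2$grid$values, expected, tolerance = 1e-10)
})

test_that("resampling outside support zero-fills and flags", {
  g <- uniform_grid(5, c(4, 4, 4), spacing = 1)
  rs <- resample_onto(g, origin = c(-2, 0, 0), spacing = c(1, 1, 1),
                      dim = c(4, 4, 4))
  expect_true(any(rs$out_of_support$values))
  expect_equal(unique(rs$grid$values[rs$out_of_support$values]), 0)
  expect_equal(unique(rs$grid$values[!rs$out_of_support$values]), 5)
  expect_error(resample_onto(g, origin = c(0, 0, 0), spacing = c(0, 1, 1),
                             dim = c(2, 2, 2)), "geometry error")
})

test_that("structure_mask enforces geometry agreement", {
  g <- uniform_grid(1, c(3, 3, 3))
  expect_error(structure_mask(array(TRUE, c(2, 2, 2)), g), "geometry")
  m <- structure_mask(array(TRUE, c(3, 3, 3)), g, role = "target")
  expect_equal(m$role, "target")
})
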