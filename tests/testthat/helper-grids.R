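# fixtures are built in code: small random paired grids and degenerate cases

uniform_grid <- function(value = 50, shape = c(6, 6, 6), spacing = 2.5) {
  dose_grid(array(value, shape), spacing = rep(spacing, 3))
}

# paired ref/eval grids with smooth-ish multiplicative differences
random_pair <- function(shape = c(9, 9, 9), spacing = c(3, 3, 3),
                        rel_sd = 0.02, seed = 1) {
  set.seed(seed)
  ref <- dose_grid(array(runif(prod(shape), 10, 60), shape), spacing = spacing)
  ev <- dose_grid(pmax(ref$values * (1 + array(rnorm(prod(shape), 0, rel_sd),
                                               shape)), 0),
                  ref$origin, ref$spacing)
  list(ref = ref, ev = ev)
}

small_plan_cfg <- function(...) {
  plan_sim_config(shape = c(32, 32, 32), spacing = c(2.5, 2.5, 2.5),
                  radii = c(16, 13, 11), falloff = 8, ...)
}

expect_identity_holds <- function(ct) {
  expect_equal(ct$passed_both,
               100 - ct$failed_gamma - ct$failed_dd + ct$failed_both,
               tolerance = 1e-12)
}
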