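test_that("build_grid constructs a valid edge-refined mesh", {
  g <- build_grid(1, grid_spec(t_start = 1e-4, t_end = 1, n_z = 8))
  expect_true(all(g$r >= 0 & g$r <= g$r_max))
  expect_true(all(g$z >= 0 & g$z <= 1))
  expect_true(any(g$r == 0) && any(g$r == 1))
  # spacing grows by at most the expansion factor away from the disk edge
  # (snapped end intervals may merge up to one extra spacing)
  hr <- diff(g$r)
  ratio <- pmax(hr[-1] / hr[-length(hr)], hr[-length(hr)] / hr[-1])
  expect_true(all(ratio <= 2 * g$spec$r_expansion + 1e-9))
  # thin-cuticle experimental geometry stays well under the node budget
  g2 <- build_grid(1.1111e-4, grid_spec(t_start = 1e-11, t_end = 1e-5))
  expect_gte(g2$nz, 8)
  expect_lt(g2$nr * g2$nz, 5e5)
  expect_error(build_grid(1, grid_spec(t_start = 1e-4, t_end = 1, n_z = 8, h_min = 0.5)),
               "h_min")
})

test_that("step_implicit preserves steady state, bounds and first-order consistency", {
  g <- build_grid(0.5, grid_spec(t_start = 1e-3, t_end = 1, n_z = 8))
  ones <- matrix(1, g$nr, g$nz)
  expect_equal(step_implicit(ones, 0.01, g), ones, tolerance = 1e-9)
  zero <- matrix(0, g$nr, g$nz)
  C1 <- step_implicit(zero, 1e-3, g)
  expect_true(all(C1 >= -1e-12 & C1 <= 1 + 1e-12))
  # two half-steps are closer to a fine reference than one full step (O(dT^2))
  dT <- 0.02
  fine <- Reduce(function(C, .) step_implicit(C, dT / 16, g), 1:16, accumulate = FALSE,
                 init = zero)
  full <- step_implicit(zero, dT, g)
  half <- step_implicit(step_implicit(zero, dT / 2, g), dT / 2, g)
  err_full <- max(abs(full - fine))
  err_half <- max(abs(half - fine))
  expect_lt(err_half, 0.7 * err_full)
  expect_error(step_implicit(zero, -1, g), "positive")
})

test_that("simulated curves satisfy the maximum principle, monotonicity and mass balance", {
  crv <- sim_thin()
  expect_true(all(diff(crv$M) > 0))
  expect_true(all(crv$rate > 0))
  expect_lt(attr(crv, "mass_balance"), 0.01)
  # flux-quadrature and mass-differentiation rates agree away from the ends
  mid <- seq(5, nrow(crv) - 5)
  expect_true(all(abs(crv$rate_m[mid] / crv$rate[mid] - 1) < 0.02))
  # the saturated-cylinder mass below the disk is exceeded at long times
  expect_gt(max(crv$M), pi * 0.01)
})

test_that("1D mode matches the Crank series and conserves the slab mass", {
  crv <- sim_1d_thin()
  z <- 0.01
  an <- crank_rate(crv$T, z)
  expect_true(all(abs(crv$rate / an - 1) < 0.005))
  # fully saturated slab under the disk: M -> A_d * z
  expect_equal(max(crv$M), pi * z, tolerance = 1e-4)
  # rate at the transition time is ~0.73 x Cottrell
  iT <- which.min(abs(crv$T - 0.5 * z^2))
  expect_equal(crv$rate[iT] / cottrell_rate(crv$T[iT]), 0.73, tolerance = 0.01)
})

test_that("refining the grid and time step leaves M(T_end) unchanged within 0.5 %", {
  z <- 0.1
  coarse <- simulate_uptake(z, grid_spec(t_start = 1e-4, t_end = 1e-1,
                                         steps_per_decade = 40, n_z = 10))
  fine <- simulate_uptake(z, grid_spec(t_start = 1e-4, t_end = 1e-1,
                                       steps_per_decade = 80, n_z = 20,
                                       h_min = min(z / 8, 5e-4)))
  expect_equal(max(coarse$M), max(fine$M), tolerance = 5e-3)
})
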