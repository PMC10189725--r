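test_that("per-particle mass and surface density reproduce the measured system", {
  expect_equal(particle_mass(2.3, 1.5), 3.45)
  # count density that closes on the printed 1.2 ug cm^-2
  expect_equal(interior_particle_density(3.48e5, 2.3, 1.5), 1.2, tolerance = 1e-3)
  expect_equal(interior_particle_density(0, 2.3, 1.5), 0)
  expect_error(interior_particle_density(NA, 2.3, 1.5), "insufficient data")
})

test_that("spacing from density follows the inverse-square-root lattice law", {
  x <- spacing_from_density(1.2, 3.45)
  expect_equal(x, 17.0, tolerance = 0.01) # consistent with the measured 17.2 um
  expect_equal(spacing_from_density(4 * 1.2, 3.45), x / 2, tolerance = 1e-12)
  # density equal to the per-particle mass per cm^2 gives 1 cm spacing
  expect_equal(spacing_from_density(3.45e-6, 3.45), 1e4)
  # hexagonal packing spreads the same mass a little wider
  expect_equal(spacing_from_density(1.2, 3.45, "hexagonal") / x,
               sqrt(2 / sqrt(3)), tolerance = 1e-12)
  # inverse of interior_particle_density at fixed per-particle mass
  dens <- interior_particle_density(3.48e5, 2.3, 1.5)
  expect_equal(spacing_from_density(dens, particle_mass(2.3, 1.5)),
               1e4 / sqrt(3.48e5), tolerance = 1e-12)
})

test_that("diffusion-zone overlap time is quadratic in the spacing", {
  expect_equal(overlap_time(17.2, 1e-10), 2.96, tolerance = 1e-3)
  expect_equal(overlap_time(10, 1e-10), 1.0)
  for (x in c(3, 17.2, 40))
    expect_equal(overlap_time(2 * x), 4 * overlap_time(x), tolerance = 1e-12)
})

test_that("ring mass fraction partitions the deposit as measured", {
  expect_equal(ring_mass_fraction(0.64, 0.16, 1.2, 58.4), 0.902, tolerance = 1e-3)
  expect_equal(ring_mass_fraction(1, 0.5, 2, 2), 0.5)
  expect_equal(ring_mass_fraction(1, 0.3, 1, 0), 0)
  f <- ring_mass_fraction(runif(20, 0.1, 2), runif(20, 0.05, 0.95),
                          runif(20, 0, 10), runif(20, 0, 100))
  expect_true(all(f >= 0 & f <= 1))
  expect_error(ring_mass_fraction(1, 1.2, 1, 1), "between 0 and 1")
})

test_that("applied dose is the volume-concentration-count product", {
  expect_equal(applied_dose(0.2, 375, 20), 1.5)
  expect_equal(applied_dose(0.2, 375, 1), 0.075)
  expect_equal(applied_dose(0.2, 0, 20), 0)
  expect_equal(applied_dose(0.4, 375, 20), 2 * applied_dose(0.2, 375, 20))
})

test_that("deposit_metrics bundles the derived quantities consistently", {
  m <- deposit_metrics(deposit_observation())
  expect_equal(m$particle_mass_pg, 3.45)
  expect_equal(m$ring_mass_fraction, 0.90, tolerance = 0.01)
  expect_equal(m$overlap_time_s, 2.96, tolerance = 1e-3)
  expect_equal(m$x_sep_implied_um, 17.0, tolerance = 0.01)
})
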