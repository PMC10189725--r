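test_that("Cottrell rate has its closed form and domain checks", {
  expect_equal(cottrell_rate(1), sqrt(pi))
  expect_equal(cottrell_rate(pi), 1)
  expect_equal(cottrell_rate(1e-6), sqrt(pi / 1e-6), tolerance = 1e-12)
  expect_true(all(diff(cottrell_rate(10^seq(-6, 2, by = 0.5))) < 0))
  expect_error(cottrell_rate(0), "positive")
  expect_error(cottrell_rate(-1), "positive")
})

test_that("Shoup-Szabo rate matches its limits and dominates Cottrell", {
  # frozen from the three-term literature formula at tau = 4e-6
  expect_equal(shoup_szabo_rate(1e-6), 1775.5416, tolerance = 1e-6)
  # short-time agreement with Cottrell within 0.5 %; the edge term grows as
  # ~1.77 sqrt(T), so this Cottrellian window closes near T ~ 8e-6
  Ts <- 10^seq(-8, -6, by = 0.5)
  expect_true(all(abs(shoup_szabo_rate(Ts) / cottrell_rate(Ts) - 1) < 0.005))
  expect_equal(shoup_szabo_rate(1e-4) / cottrell_rate(1e-4), 1 + 1.77 * sqrt(1e-4),
               tolerance = 1e-3)
  # steady-state disk uptake rate of 4
  expect_equal(shoup_szabo_rate(1e8), 4, tolerance = 1e-3)
  # the radial edge only ever adds flux, monotonically with T
  Ts <- 10^seq(-6, 6, by = 0.25)
  ratio <- shoup_szabo_rate(Ts) / cottrell_rate(Ts)
  expect_true(all(ratio >= 1))
  expect_true(all(diff(ratio) > 0))
  expect_error(shoup_szabo_rate(0), "positive")
})

test_that("Crank series co-converge at T = z^2 and reproduce the crossover constant", {
  for (z in c(1e-4, 1e-2, 1, 10)) {
    s <- crank_rate(z^2, z, "short")
    l <- crank_rate(z^2, z, "long")
    expect_equal(s, l, tolerance = 1e-6)
    # flux density at the crossover: 0.16960/z to printed precision
    expect_equal(s / pi * z, 0.16960, tolerance = 1e-3)
  }
  # matches an independently summed series
  expect_equal(crank_rate(0.7, 1.3), pi * oracle_crank_fd(0.7, 1.3), tolerance = 1e-10)
})

test_that("Crank rate reduces to Cottrell early and its ratio is scale-invariant", {
  z <- 0.35
  Ts <- 0.01 * z^2
  expect_equal(crank_rate(Ts, z), cottrell_rate(Ts), tolerance = 1e-9)
  # ratio to Cottrell depends only on T/z^2
  for (u in c(0.3, 0.72, 2)) {
    ratios <- vapply(c(1e-3, 0.1, 5), function(zz)
      crank_rate(u * zz^2, zz) / cottrell_rate(u * zz^2), numeric(1))
    expect_equal(max(ratios) - min(ratios), 0, tolerance = 1e-10)
  }
  # frozen theta-series value at u = 0.72
  expect_equal(crank_rate(0.72, 1) / cottrell_rate(0.72), 0.509020, tolerance = 1e-5)
  # saturation only ever removes flux
  Ts <- 10^seq(-4, 2, by = 0.5)
  expect_true(all(crank_rate(Ts, 1) <= cottrell_rate(Ts) + 1e-12))
  expect_error(crank_rate(1, -1), "positive")
})

test_that("cylinder rate meets its limit contracts against the FD radial oracle", {
  z <- 1.1111e-4
  # short-time planar limit: A_c / sqrt(pi T) within 1 %
  expect_equal(cylinder_rate(1e-6, z), 2 * pi * z / sqrt(pi * 1e-6), tolerance = 1e-2)
  # monotone decreasing over the contract window
  Ts <- 10^seq(-3, 3, by = 0.25)
  expect_true(all(diff(cylinder_rate(Ts, z)) < 0))
  # within 2 % of an independent finite-difference exterior-cylinder solver
  tq <- 10^seq(-3, 3, by = 1)
  fd <- oracle_radial_cylinder(tq)
  st <- cylinder_rate(tq, z) / (2 * pi * z)
  expect_true(all(abs(st / fd - 1) < 0.02))
  # logarithmic (slower than any power-law) decay at long times:
  # rate(100 T)/rate(T) approaches 1 from below as T grows
  r1 <- cylinder_rate(1e4, z) / cylinder_rate(1e2, z)
  r2 <- cylinder_rate(1e6, z) / cylinder_rate(1e4, z)
  expect_true(r1 < 1 && r2 < 1 && r2 > r1)
})

test_that("composite thin-cuticle curve hits both limits and refuses thick cuticles", {
  z <- 1e-3
  expect_equal(composite_rate(1e-4 * z^2, z), cottrell_rate(1e-4 * z^2), tolerance = 3e-3)
  expect_equal(composite_rate(1e4 * z^2, z), cylinder_rate(1e4 * z^2, z), tolerance = 1e-6)
  expect_error(composite_rate(1, 0.2), "thin")
})

test_that("limit_curves tabulates tidily and drops composite for thick cuticles", {
  lc <- limit_curves(0.01, 1e-6, 1e-2, n = 40)
  expect_s3_class(lc, "tbl_df")
  expect_setequal(unique(lc$curve),
                  c("cottrell", "shoup_szabo", "crank", "cylinder", "composite"))
  expect_true(all(lc$rate > 0))
  lc2 <- limit_curves(2, 1e-4, 1, n = 10)
  expect_false("composite" %in% lc2$curve)
})
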