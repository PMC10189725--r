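test_that("geometry and reference scales reproduce the worked examples", {
  geom <- disk_geometry(450e-6, 50e-9)
  expect_equal(geom$z_ratio, 1.1e-4, tolerance = 0.01)
  expect_equal(disk_geometry(1, 1)$z_ratio, 1)
  expect_equal(disk_geometry(450e-6, 25e-9)$z_ratio, 5.556e-5, tolerance = 1e-4)
  expect_equal(geom$a_disk, pi)
  expect_equal(geom$a_cyl, 2 * pi * geom$z_ratio)
  sc <- reference_scales(geom, 1.24e-18, 1.87e6)
  expect_equal(sc$t_ref_s, (450e-6)^2 / 1.24e-18, tolerance = 1e-12)
  expect_equal(sc$t_ref_s, 1.633e11, tolerance = 1e-3)
  expect_equal(sc$m_ref_g, 1.704e-4, tolerance = 1e-3)
  expect_equal(reference_scales(disk_geometry(1, 1), 1, 1)$t_ref_s, 1)
  expect_error(disk_geometry(-1, 1), "positive")
  expect_error(reference_scales(geom, 0, 1), "positive")
})

test_that("transition time follows 0.5 z^2 and sits at ~17 min for the fitted scales", {
  expect_equal(transition_time(1), 0.5)
  expect_equal(transition_time(1.1111e-4), 6.17e-9, tolerance = 1e-3)
  # dimensional transition for the fitted reference time: about 17 min,
  # the same order as the observed early-uptake window
  t_min <- transition_time(1.1111e-4) * 1.633e11 / 60
  expect_gt(t_min, 5); expect_lt(t_min, 60)
})

test_that("dimensionalize is the exact inverse of nondimensionalize", {
  crv <- tibble::tibble(T = 10^seq(-9, -6, by = 0.25),
                        M = 10^seq(-6, -3, by = 0.25),
                        rate = 1 / sqrt(10^seq(-9, -6, by = 0.25)))
  dim <- dimensionalize(crv, t_ref_s = 1.6e11, m_ref_ug = 170, n_droplets = 20)
  back <- nondimensionalize(dim, t_ref_s = 1.6e11, m_ref_ug = 170, n_droplets = 20)
  expect_equal(back$T, crv$T, tolerance = 1e-14)
  expect_equal(back$M, crv$M, tolerance = 1e-14)
  # identity scales return the curve itself; droplet count only scales mass
  ident <- dimensionalize(crv, 1, 1, 1)
  expect_equal(ident$time_s, crv$T)
  expect_equal(ident$mass_ug, crv$M)
  expect_equal(dimensionalize(crv, 1, 1, 2)$mass_ug, 2 * crv$M)
})

test_that("partition coefficient and pathway criterion behave as documented", {
  expect_equal(csat_to_kcw(1, 1)$log10_k_cw, 0)
  expect_equal(csat_to_kcw(1.87e6, 1.87)$log10_k_cw, 6)
  expect_error(csat_to_kcw(0, 1), "positive")
  g <- pathway_criterion(1.24e-18, 1.87e6, 1e-10, 1)
  expect_equal(g$g, 2.32e-2, tolerance = 1e-3)
  expect_identical(g$regime, "indirect-dominant")
  expect_identical(pathway_criterion(1, 1, 1, 1)$regime, "balanced")
  expect_error(pathway_criterion(1e-18, 1e6), "insufficient data")
  # G strictly increasing in D_cut
  expect_gt(pathway_criterion(2e-18, 1.87e6, 1e-10, 1)$g, g$g)
})

test_that("fit recovers noiseless truth and responds linearly to mass rescaling", {
  geom <- disk_geometry(450e-6, 50e-9, 20)
  master <- master_maize()
  a0 <- gen_assay(master, geom, 1.24e-18, 1.87e6, cv = 0, seed = 1)
  f0 <- fit_uptake(a0, master, geom)
  td <- tidy(f0)
  est <- setNames(td$estimate, td$term)
  expect_equal(est[["d_cut_m2_s"]], 1.24e-18, tolerance = 0.01)
  expect_equal(est[["c_sat_cut_ppm"]], 1.87e6, tolerance = 0.01)
  expect_gt(glance(f0)$r.squared, 0.999)
  # scaling every mass by k moves m_ref by k and leaves t_ref fixed
  a_scaled <- dplyr::mutate(a0, mass_TL_ug = mass_TL_ug * 3)
  f3 <- fit_uptake(a_scaled, master, geom)
  e3 <- setNames(tidy(f3)$estimate, tidy(f3)$term)
  expect_equal(e3[["m_ref_ug"]], 3 * est[["m_ref_ug"]], tolerance = 1e-4)
  expect_equal(e3[["t_ref_s"]], est[["t_ref_s"]], tolerance = 1e-4)
  expect_equal(e3[["d_cut_m2_s"]], est[["d_cut_m2_s"]], tolerance = 1e-4)
  # the objective is invariant to row order
  f_shuf <- withr::with_seed(42, fit_uptake(a0[sample(nrow(a0)), ], master, geom))
  expect_equal(setNames(tidy(f_shuf)$estimate, tidy(f_shuf)$term), est, tolerance = 1e-8)
})

test_that("fit validates its inputs", {
  geom <- disk_geometry(450e-6, 50e-9, 20)
  master <- master_maize()
  expect_error(fit_uptake(tibble::tibble(time_min = 1, mass = 1), master, geom),
               "time_min")
  few <- tibble::tibble(time_min = c(0, 10, 10), mass_TL_ug = c(0, 1, 1.1))
  expect_error(fit_uptake(few, master, geom), "3 distinct")
  narrow <- tibble::tibble(time_min = c(10, 20, 30, 40), mass_TL_ug = c(1, 1.2, 1.3, 1.35))
  expect_warning(fit_uptake(narrow, master, geom), "decade")
})
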