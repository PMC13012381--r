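test_that("degenerate sources produce empty dose grids", {
  ph <- fixture_water_box(20, 20, 10)
  g0 <- simulate_dose(ph, fixture_geometry(5, 2), generate_spectrum(120),
                      n_photons = 0, n_batches = 2, seed = 1)
  expect_true(all(g0$grid == 0))
  # near-vacuum phantom: no interactions, no deposit
  vac <- ph
  vac$density <- array(1e-12, dim(ph$hu))
  gv <- simulate_dose(vac, fixture_geometry(5, 2), generate_spectrum(120),
                      n_photons = 1e4, n_batches = 2, seed = 1)
  expect_equal(sum(gv$deposited_keV), 0)
  expect_error(simulate_dose(ph, fixture_geometry(5, 2),
                             generate_spectrum(120), n_photons = 10,
                             n_batches = 1), "batches")
})

test_that("simulation is deterministic for a fixed seed", {
  ph <- fixture_water_box(20, 20, 10)
  g1 <- simulate_dose(ph, fixture_geometry(5, 2), generate_spectrum(120),
                      n_photons = 2e4, n_batches = 4, seed = 42)
  g2 <- simulate_dose(ph, fixture_geometry(5, 2), generate_spectrum(120),
                      n_photons = 2e4, n_batches = 4, seed = 42)
  expect_identical(g1$grid, g2$grid)
  g3 <- simulate_dose(ph, fixture_geometry(5, 2), generate_spectrum(120),
                      n_photons = 2e4, n_batches = 4, seed = 43)
  expect_false(identical(g1$grid, g3$grid))
})

test_that("energy is conserved in every batch", {
  pp <- fixture_pelvis()
  p <- get_protocol("F6", "pelvis")
  g <- simulate_dose(pp$phantom, derive_geometry(p),
                     generate_spectrum(p$kvp), bowtie_profile(p$bowtie),
                     n_photons = 1e5, n_batches = 10, seed = 7)
  expect_true(all(g$deposited_keV <= g$emitted_keV))
  expect_true(all(g$deposited_keV > 0))
})

test_that("narrow-beam transmission matches Beer-Lambert within 3 sigma", {
  ph <- fixture_water_box(60, 40, 20)   # 20 cm of water along y
  n <- 2e5
  tf <- transmission_fraction(ph, 60, source_mm = c(0, 400, 0),
                              direction = c(0, -1, 0), n_photons = n,
                              seed = 11)
  p_true <- exp(-material_mu("water", 60) * 1.0 * 20)
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(tf - p_true), 3 * se)
})

test_that("Compton sampling obeys kinematics and Klein-Nishina moments", {
  sm <- sample_compton(2e5, 100, seed = 3)
  expect_true(all(sm[, "scattered_keV"] <= 100 + 1e-12))
  # energy-angle relation exact for every sample
  ep <- 100 / (1 + 100 / 510.999 * (1 - sm[, "cos_theta"]))
  expect_equal(unname(sm[, "scattered_keV"]), unname(ep), tolerance = 1e-12)
  # mean cos(theta) vs numeric quadrature of the Klein-Nishina pdf
  a <- 100 / 510.999
  cth <- seq(-1, 1, length.out = 20001)
  x <- 1 / (1 + a * (1 - cth))
  dcs <- x^2 * (x + 1 / x - (1 - cth^2))
  mu_true <- sum(dcs * cth) / sum(dcs)
  se <- sd(sm[, "cos_theta"]) / sqrt(nrow(sm))
  expect_lt(abs(mean(sm[, "cos_theta"]) - mu_true), 3 * se)
  # repeatability
  expect_identical(sample_compton(100, 80, seed = 5),
                   sample_compton(100, 80, seed = 5))
})

test_that("free-in-air kerma matches the analytic estimator", {
  mono <- fixture_monospectrum(60, kvp = 120)
  g <- fixture_geometry(10, 8)
  k <- score_air_kerma_free_in_air(g, mono, n_photons = 4e5, seed = 21)
  A <- 20 * 16
  expected <- 60 * material_muen("air", 60) / A
  expect_equal(k, expected, tolerance = 0.03)
  # normalization: per-photon kerma independent of photon count
  k2 <- score_air_kerma_free_in_air(g, mono, n_photons = 8e5, seed = 22)
  expect_equal(k, k2, tolerance = 0.03)
  # inverse square at twice the source distance
  k_far <- score_air_kerma_free_in_air(g, mono, point_mm = c(0, -1000, 0),
                                       n_photons = 4e5, seed = 23)
  expect_equal(k / k_far, 4, tolerance = 0.1)
  expect_error(score_air_kerma_free_in_air(g, mono,
                                           point_mm = c(500, 0, 0)),
               "outside the beam")
})
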