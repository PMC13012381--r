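make_dose_grid <- function(grid, spacing_mm, origin_mm, batch_organ = NULL,
                           n_batches = 2) {
  structure(list(grid = grid, batch_organ = batch_organ,
                 emitted_keV = rep(1, n_batches),
                 deposited_keV = rep(0.5, n_batches),
                 n_photons = 1, n_batches = n_batches,
                 seed = 1, spacing_mm = spacing_mm, origin_mm = origin_mm,
                 unit = "test"), class = "dose_grid")
}

test_that("CTDI_w weighting identities hold exactly", {
  ct <- make_ctdi_phantom(32)
  dm <- dim(ct$phantom$hu)
  # uniform field: every probe reads d, CTDI_w = d
  g <- make_dose_grid(array(7, dm), ct$phantom$spacing_mm,
                      ct$phantom$origin_mm)
  res <- compute_ctdiw(g, ct$probes_mm, collimation_cm = 10)
  expect_equal(unname(res$ctdi100), rep(7, 5))
  expect_equal(res$ctdiw, 7)
  # centre 9, periphery 12 -> 9/3 + 2*12/3 = 11
  cx <- voxel_centers(ct$phantom, 1)
  cy <- voxel_centers(ct$phantom, 2)
  ring <- array(12, dm)
  inner <- outer(cx^2, cy^2, "+") <= 50^2
  ring[array(rep(inner, dm[3]), dm)] <- 9
  g2 <- make_dose_grid(ring, ct$phantom$spacing_mm, ct$phantom$origin_mm)
  res2 <- compute_ctdiw(g2, ct$probes_mm, collimation_cm = 10)
  expect_equal(res2$ctdiw, 11)
  # invariant for any computed result
  expect_equal(res2$ctdiw,
               res2$ctdi100_centre / 3 + 2 * res2$ctdi100_periphery_mean / 3)
  # per-100-mAs normalization
  res3 <- compute_ctdiw(g, ct$probes_mm, collimation_cm = 10, mas = 200)
  expect_equal(res3$ctdiw_per_100mas, 3.5)
  # integration range must be covered
  short <- make_ctdi_phantom(32, length_cm = 15)
  gs <- make_dose_grid(array(1, dim(short$phantom$hu)),
                       short$phantom$spacing_mm,
                       c(short$phantom$origin_mm[1:2], -30))
  expect_error(compute_ctdiw(gs, short$probes_mm, 10), "exceeds")
})

test_that("simulated CTDI periphery exceeds the centre at 120 kV", {
  conv <- fixture_conversion(120, "elekta_half")
  expect_gt(conv$ctdi$ctdi100_periphery_mean, conv$ctdi$ctdi100_centre)
  expect_gt(conv$factor, 0)
})

test_that("normalization closes the CTDI_w chain and is linear", {
  conv <- fixture_conversion(120, "elekta_half")
  # independent re-simulation of the conversion setup, scaled by the
  # factor chain, must reproduce a target CTDI_w within MC noise
  target <- as_protocol(list(hospital = "t", vendor_model = "Elekta x",
                             kvp = 120, mas = 100, ctdiw_mGy = 13.7,
                             n_projections = 360, start_angle = -180,
                             stop_angle = 180, scan_length_cm = 10,
                             fov_cm = 26, fan_mode = "full",
                             bowtie = "elekta_half"))
  g2 <- simulate_dose(conv$ct$phantom, conv$geom, conv$spec, conv$bowtie,
                      n_photons = 6e5, n_batches = 10, seed = 881)
  ka2 <- score_air_kerma_free_in_air(conv$geom, conv$spec, conv$bowtie,
                                     n_photons = 6e5, seed = 882)
  g2n <- normalize_to_protocol(g2, target, conv$factor, ka2)
  ctdi2 <- compute_ctdiw(g2n, conv$ct$probes_mm, collimation_cm = 10)
  expect_equal(ctdi2$ctdiw, 13.7, tolerance = 0.06)
  # doubling the printed CTDI_w doubles every voxel dose exactly
  tgt2 <- target; tgt2$ctdiw_mGy <- 2 * target$ctdiw_mGy
  g2n2 <- normalize_to_protocol(g2, tgt2, conv$factor, ka2)
  expect_equal(g2n2$grid, 2 * g2n$grid, tolerance = 1e-12)
  expect_error(normalize_to_protocol(g2, target, conv$factor, 0),
               "positive")
})

test_that("organ means equal brute-force averages over the masks", {
  dm <- c(4, 3, 2)
  lab <- array(0L, dm)
  lab[1:3, 1, 1] <- 1L
  masks <- structure(list(labels = lab, organs = c(roi = 1L),
                          spacing_mm = c(5, 5, 5),
                          origin_mm = c(0, 0, 0)), class = "organ_masks")
  grid <- array(0, dm)
  grid[1:3, 1, 1] <- c(1, 2, 6)
  g <- make_dose_grid(grid, c(5, 5, 5), c(0, 0, 0))
  rep_ <- organ_mean_doses(g, masks)
  expect_equal(rep_$dose, 3)
  expect_equal(rep_$n_voxels, 3)
  # uniform field: every organ mean equals the field value
  pp <- fixture_pelvis()
  gu <- make_dose_grid(array(2.5, dim(pp$phantom$hu)),
                       pp$phantom$spacing_mm, pp$phantom$origin_mm)
  ru <- organ_mean_doses(gu, pp$masks)
  expect_equal(ru$dose, rep(2.5, nrow(ru)))
  # random grid vs independent summation oracle
  set.seed(31)
  gr <- array(runif(prod(dim(pp$phantom$hu))), dim(pp$phantom$hu))
  gg <- make_dose_grid(gr, pp$phantom$spacing_mm, pp$phantom$origin_mm)
  rr <- organ_mean_doses(gg, pp$masks)
  idx <- organ_indices(pp$masks, "rectum")
  expect_equal(rr$dose[rr$organ == "rectum"], sum(gr[idx]) / length(idx),
               tolerance = 1e-12)
  # empty mask errors with the organ name
  m2 <- pp$masks
  m2$organs <- c(m2$organs, ghost = 99L)
  expect_error(organ_mean_doses(gg, m2), "ghost")
})

test_that("bootstrap uncertainty behaves like the analytic SEM", {
  expect_equal(unname(bootstrap_uncertainty(rep(3, 20))), 0)
  b1 <- bootstrap_uncertainty(1:10, seed = 4)
  b2 <- bootstrap_uncertainty(1:10, seed = 4)
  expect_identical(b1, b2)
  set.seed(88)
  x <- rnorm(50, 10, 2)
  se_boot <- unname(bootstrap_uncertainty(x, n_resamples = 2000, seed = 9))
  expect_equal(se_boot, sd(x) / sqrt(50), tolerance = 0.2)
  expect_error(bootstrap_uncertainty(1), "at least 2")
})

test_that("RBM conversion weights and bounds follow the factor table", {
  spec <- generate_spectrum(120)
  # identity table leaves the spongiosa dose unchanged
  idpath <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(site = "femora", energy_keV = c(10, 150),
                       meac_ratio = 1, def = 1), idpath, row.names = FALSE)
  expect_equal(as.numeric(rbm_dose(5, spec, "femora",
                                   rbm_factors(idpath))), 5)
  # monoenergetic spectrum at a table node gives the node product
  fac <- rbm_factors()
  tab <- fac$pelvis
  mono <- fixture_monospectrum(60, kvp = 120)
  d <- rbm_dose(2, mono, "pelvis", fac)
  i <- which(tab$energy_keV == 60)
  expect_equal(as.numeric(d), 2 * tab$meac_ratio[i] * tab$def[i],
               tolerance = 1e-9)
  # two-bin spectrum vs hand-computed weighted sums
  e <- 5:120
  f <- as.numeric(e == 40) * 2 + as.numeric(e == 80)
  two <- cbctdose:::new_energy_spectrum(e, f, 120)
  w <- f[f > 0] * c(40, 80) * material_muen("spongiosa", c(40, 80))
  r <- sapply(c(40, 80), function(en)
    tab$meac_ratio[tab$energy_keV == en])
  dd <- sapply(c(40, 80), function(en) tab$def[tab$energy_keV == en])
  expected <- 3 * sum(w * r) / sum(w) * sum(w * dd) / sum(w)
  expect_equal(as.numeric(rbm_dose(3, two, "pelvis", fac)), expected,
               tolerance = 1e-9)
  # weighted averages bounded by the table extrema for any tube spectrum
  for (kvp in c(100, 120, 125)) {
    s <- generate_spectrum(kvp)
    for (site in c("femora", "pelvis", "sacrum")) {
      d1 <- rbm_dose(1, s, site, fac)
      tb <- fac[[site]]
      expect_gte(attr(d1, "meac_ratio_w"), min(tb$meac_ratio))
      expect_lte(attr(d1, "meac_ratio_w"), max(tb$meac_ratio))
      expect_gte(attr(d1, "def_w"), min(tb$def))
      expect_lte(attr(d1, "def_w"), max(tb$def))
    }
  }
  expect_error(rbm_dose(1, spec, "skull", fac), "not tabulated")
})

test_that("ROI means agree with brute-force voxel enumeration", {
  pp <- fixture_pelvis()
  dm <- dim(pp$phantom$hu)
  set.seed(12)
  gr <- array(runif(prod(dm)), dm)
  g <- make_dose_grid(gr, pp$phantom$spacing_mm, pp$phantom$origin_mm)
  expect_equal(roi_mean_dose(g, list(type = "box",
                                     lower_mm = c(-1e4, -1e4, -1e4),
                                     upper_mm = c(1e4, 1e4, 1e4))),
               mean(gr))
  u <- make_dose_grid(array(4, dm), pp$phantom$spacing_mm,
                      pp$phantom$origin_mm)
  expect_equal(roi_mean_dose(u, list(type = "sphere",
                                     center_mm = c(0, 0, 0),
                                     radius_mm = 30)), 4)
  # sphere vs manual enumeration
  cx <- voxel_centers(pp$phantom, 1)
  cy <- voxel_centers(pp$phantom, 2)
  cz <- voxel_centers(pp$phantom, 3)
  sel <- array(FALSE, dm)
  for (k in seq_len(dm[3]))
    sel[, , k] <- outer((cx - 10)^2, (cy + 20)^2, "+") + (cz[k] - 5)^2 <=
      40^2
  expect_equal(roi_mean_dose(g, list(type = "sphere",
                                     center_mm = c(10, -20, 5),
                                     radius_mm = 40)),
               mean(gr[sel]), tolerance = 1e-12)
  expect_error(roi_mean_dose(g, list(type = "sphere",
                                     center_mm = c(0, 0, 1e5),
                                     radius_mm = 1)), "intersect")
})

test_that("quadrature combination of uncertainties", {
  expect_equal(combine_uncertainties(7), 7)
  expect_equal(combine_uncertainties(c(3, 4)), 5)
  expect_equal(combine_uncertainties(c(13, 10)), sqrt(269))
  expect_error(combine_uncertainties(c(-1, 2)))
})
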