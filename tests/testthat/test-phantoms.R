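test_that("CTDI phantom geometry and mass are correct", {
  ct <- make_ctdi_phantom(32, spacing_mm = 2.5)
  ph <- ct$phantom
  expect_equal(unname(ct$probes_mm["centre", ]), c(0, 0))
  expect_equal(sqrt(sum(ct$probes_mm["N", ]^2)), 150)  # 1 cm depth
  vox_cm3 <- prod(ph$spacing_mm / 10)
  mass <- sum(ph$density[ph$material == 2L]) * vox_cm3
  analytic <- pi * 16^2 * 15 * 1.19
  expect_equal(mass, analytic, tolerance = 0.01)
  expect_error(make_ctdi_phantom(20), "unsupported")
  expect_error(make_ctdi_phantom(32, spacing_mm = 8), "spacing")
})

test_that("the default pelvis phantom has disjoint, well-placed organs", {
  pp <- fixture_pelvis()
  masks <- pp$masks
  all_idx <- integer(0)
  for (o in pelvis_organ_names()) {
    idx <- organ_indices(masks, o)
    expect_gt(length(idx), 0)
    all_idx <- c(all_idx, idx)
  }
  expect_equal(anyDuplicated(all_idx), 0)   # pairwise disjoint
  # prostate centred on the isocentre within one voxel
  idx <- organ_indices(masks, "prostate")
  a <- arrayInd(idx, dim(masks$labels))
  centroid <- vapply(1:3, function(k) {
    mean(masks$origin_mm[k] + (a[, k] - 0.5) * masks$spacing_mm[k])
  }, numeric(1))
  expect_true(all(abs(centroid) <= masks$spacing_mm))
  # prostate volume near the analytic 25 cm^3 ellipsoid
  vol <- length(idx) * prod(masks$spacing_mm / 10)
  expect_equal(vol, 25, tolerance = 0.2)
})

test_that("phantom generation is deterministic and reports collisions", {
  a <- make_pelvis_phantom(seed = 7, jitter_mm = 2)
  b <- make_pelvis_phantom(seed = 7, jitter_mm = 2)
  expect_identical(a$phantom$hu, b$phantom$hu)
  expect_identical(a$masks$labels, b$masks$labels)
  # moving the bladder onto the prostate must error, not overlap
  bad <- pelvis_phantom_params()
  bad$bladder_center_cm <- c(0, 0, 1)
  expect_error(make_pelvis_phantom(params = bad), "collides")
})

test_that("hu_to_material is total and monotone in density", {
  m <- hu_to_material(c(-1000, 0))
  expect_equal(m$material_names[m$material_index], c("air", "soft_tissue"))
  expect_equal(m$density, c(0.0012, 1.00), tolerance = 1e-9)
  sweep <- hu_to_material(seq(-1000, 2000, by = 1))
  expect_true(all(diff(sweep$density) >= 0))
  expect_true(all(sweep$material_index %in% 1:5))
  # out-of-range values clamp rather than error
  expect_silent(hu_to_material(c(-5000, 5000)))
})

test_that("volumes round-trip losslessly through NIfTI", {
  pp <- fixture_pelvis()
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(pp$phantom, path)
  r <- read_volume(path)
  expect_equal(r$hu, pp$phantom$hu, ignore_attr = TRUE)
  expect_equal(r$spacing_mm, pp$phantom$spacing_mm, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(r$origin_mm, pp$phantom$origin_mm, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_error(read_volume(file.path(tempdir(), "nope.nii")), "no such file")
})

test_that("voxelized body mass converges under spacing refinement", {
  coarse <- fixture_pelvis()$phantom
  fine <- make_pelvis_phantom(spacing_mm = 2.5)$phantom
  mass <- function(ph) {
    m <- hu_to_material(ph$hu)
    sel <- m$material_index > 1
    sum(m$density[sel]) * prod(ph$spacing_mm / 10)
  }
  expect_equal(mass(coarse), mass(fine), tolerance = 0.02)
})

test_that("synthetic survey records are reproducible with the stated law", {
  a <- generate_survey_records(seed = 5)
  b <- generate_survey_records(seed = 5)
  expect_identical(a, b)
  expect_named(a, c("country", "hospital", "site", "ctdiw_mGy",
                    "imaging_frequency"))
  deg <- generate_survey_records(meanlog = log(10), sdlog = 0, seed = 2)
  expect_equal(deg$ctdiw_mGy, rep(10, nrow(deg)))
  big <- generate_survey_records(n_countries = 1,
                                 hospitals_per_country = 4000,
                                 protocols_per_hospital = 1,
                                 meanlog = log(12), sdlog = 0.4, seed = 9)
  expect_equal(unname(quantile(big$ctdiw_mGy, 0.75)),
               qlnorm(0.75, log(12), 0.4), tolerance = 0.02)
})
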