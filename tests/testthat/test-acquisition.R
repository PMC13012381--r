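test_that("the protocol registry matches the surveyed parameter tables", {
  reg <- builtin_protocols()
  expect_equal(nrow(reg), 15)
  expect_equal(sum(reg$site == "pelvis"), 9)
  expect_equal(sum(reg$site == "prostate"), 6)
  C <- get_protocol("C", "pelvis")
  expect_equal(C$kvp, 120)
  expect_equal(C$mas, 1056)
  expect_equal(C$ctdiw_mGy, 22.0)
  expect_equal(C$n_projections, 660)
  expect_equal(C$scan_length_cm, 41)
  expect_equal(C$fov_cm, 27)
  J <- get_protocol("J", "prostate")
  expect_equal(J$kvp, 125)
  expect_equal(J$mas, 252)
  expect_equal(J$ctdiw_mGy, 3.70)
  expect_equal(J$n_projections, 900)
  expect_equal(J$fov_cm, 45)
  H1 <- get_protocol("H1 60mA", "pelvis")
  expect_equal(H1$fan_mode, "full")
  expect_error(get_protocol("G1"), "several sites")
  expect_error(get_protocol("XX", "pelvis"), "no protocol")
})

test_that("projection schedules follow the signed start-stop arc", {
  D1 <- get_protocol("D1", "pelvis")
  a <- projection_angles(D1)
  expect_length(a, 900)
  expect_equal(max(a) - min(a), 180)
  expect_equal(a[1], 90)
  expect_equal(a[length(a)], 270)

  C <- get_protocol("C", "pelvis")
  ac <- projection_angles(C)
  expect_length(ac, 660)
  expect_equal(abs(attr(ac, "arc_deg")), 360)
  expect_equal(diff(ac)[1], 360 / 660)

  single <- as_protocol(list(hospital = "t", vendor_model = "x", kvp = 120,
                             mas = 10, ctdiw_mGy = 1, n_projections = 1,
                             start_angle = 45, stop_angle = 90,
                             scan_length_cm = 10, fov_cm = 20,
                             fan_mode = "full"))
  expect_equal(as.numeric(projection_angles(single)), 45)
})

test_that("per-projection mAs weights always sum to the protocol Q", {
  reg <- builtin_protocols()
  for (i in seq_len(nrow(reg))) {
    p <- as_protocol(reg[i, ])
    a <- projection_angles(p)
    expect_equal(attr(a, "weight_mAs") * length(a), p$mas)
  }
})

test_that("derived geometry covers FOV and imaged length", {
  p45 <- as_protocol(list(hospital = "t", vendor_model = "Varian x",
                          kvp = 125, mas = 100, ctdiw_mGy = 5,
                          n_projections = 10, start_angle = -180,
                          stop_angle = 180, scan_length_cm = 15,
                          fov_cm = 45, fan_mode = "full"))
  g <- derive_geometry(p45)
  expect_equal(g$fan_half_angle_deg, atan(0.225) * 180 / pi,
               tolerance = 1e-10)
  expect_equal(g$cone_half_angle_deg, atan(0.075) * 180 / pi,
               tolerance = 1e-10)
  cg <- conversion_geometry()
  expect_equal(cg$fan_half_angle_deg, 8)
  expect_equal(2 * cg$v_half_cm, 10)

  reg <- builtin_protocols()
  for (i in seq_len(nrow(reg))) {
    p <- as_protocol(reg[i, ])
    gi <- suppressWarnings(derive_geometry(p))
    expect_gte(gi$u_max_cm, p$fov_cm / 2 - 1e-9)        # covered side
    expect_equal(2 * gi$v_half_cm, p$scan_length_cm)    # axial aperture
  }
  expect_warning(derive_geometry(get_protocol("G1", "pelvis")),
                 "coverage is incomplete")
})

test_that("bowtie profiles are minimal at their central ray and attenuate
           per Beer-Lambert", {
  bf <- bowtie_profile("varian_full")
  th <- bowtie_thickness(bf, seq(-20, 20, by = 0.5))
  expect_equal(min(th), bowtie_thickness(bf, 0))
  expect_true(all(th >= 0))
  for (nm in c("elekta_half", "varian_half")) {
    bh <- bowtie_profile(nm)
    ang <- seq(-20, 20, by = 0.25)
    expect_gt(abs(ang[which.min(bowtie_thickness(bh, ang))]), 0)  # off-centre
  }
  s <- generate_spectrum(120)
  expect_equal(bowtie_transmission(bowtie_profile("none"), 10, s)$fluence,
               s$fluence)
  # transmitted air-kerma fraction at 10 degrees vs per-bin closed form
  b <- bowtie_profile("elekta_half")
  t_mm <- bowtie_thickness(b, 10)
  out <- bowtie_transmission(b, 10, s)
  kerma <- function(sp) sum(sp$fluence * sp$energy_keV *
                              material_muen("air", sp$energy_keV))
  manual <- s$fluence * exp(-material_mu("aluminum", s$energy_keV) *
                              material_density("aluminum") * t_mm / 10)
  expect_equal(kerma(out) / kerma(s),
               sum(manual * s$energy_keV *
                     material_muen("air", s$energy_keV)) / kerma(s),
               tolerance = 1e-12)
  expect_warning(bowtie_thickness(b, 30), "clamping")
})
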