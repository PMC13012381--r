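# Shared fixtures, memoised so expensive Monte Carlo runs and the pelvis
# phantom are built once per test session.

.fixture_cache <- new.env(parent = emptyenv())

with_cache <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, expr, .fixture_cache)
  get(key, .fixture_cache)
}

fixture_pelvis <- function() with_cache("pelvis", make_pelvis_phantom())

# homogeneous water box with explicit material arrays (hu is nominal)
fixture_water_box <- function(nx = 60, ny = 60, nz = 20, spacing = 5) {
  ph <- cbctdose:::new_voxel_phantom(
    array(0, c(nx, ny, nz)), rep(spacing, 3),
    -c(nx, ny, nz) / 2 * spacing)
  ph$material <- array(2L, dim(ph$hu))
  ph$density <- array(1.0, dim(ph$hu))
  ph$material_names <- c("air", "water")
  ph
}

# spectrum with all fluence in a single bin
fixture_monospectrum <- function(energy, kvp = energy) {
  e <- seq(5, kvp, by = 1)
  cbctdose:::new_energy_spectrum(e, as.numeric(e == energy), kvp)
}

# fixed-field geometry (single projection unless angles given)
fixture_geometry <- function(u_half = 10, v_half = 10, angles = 0,
                             sid = 100) {
  structure(list(
    fan_half_angle_deg = atan(u_half / sid) * 180 / pi,
    cone_half_angle_deg = atan(v_half / sid) * 180 / pi,
    u_min_cm = -u_half, u_max_cm = u_half, v_half_cm = v_half,
    detector_offset_cm = 0, sid_cm = sid, sdd_cm = 150,
    rotation_arc_deg = if (length(angles) > 1) 360 else 0,
    projection_angles_deg = angles, weight_mAs = NA_real_,
    fan_mode = "full"), class = "beam_geometry")
}

# conversion run (CTDI grid + probes + kerma) for a kvp/bowtie pairing
fixture_conversion <- function(kvp, bowtie_name, n_photons = 1.5e6) {
  key <- paste0("conv_", kvp, "_", bowtie_name)
  with_cache(key, {
    spec <- generate_spectrum(kvp)
    bt <- bowtie_profile(bowtie_name)
    ct <- make_ctdi_phantom(32)
    geom <- conversion_geometry()
    grid <- simulate_dose(ct$phantom, geom, spec, bt,
                          n_photons = n_photons, n_batches = 10, seed = 301)
    ctdi <- compute_ctdiw(grid, ct$probes_mm, collimation_cm = 10)
    ka <- score_air_kerma_free_in_air(geom, spec, bt, n_photons = 8e5,
                                      seed = 302)
    list(spec = spec, bowtie = bt, ct = ct, geom = geom, grid = grid,
         ctdi = ctdi, ka = ka, factor = ka / ctdi$ctdiw)
  })
}

# full protocol chain at the study's desk-scale conditions
fixture_protocol_run <- function(hospital, site, n_photons = 2e6,
                                 n_batches = 50, seed = 101) {
  key <- paste0("prot_", hospital, "_", site)
  with_cache(key, {
    pp <- fixture_pelvis()
    p <- get_protocol(hospital, site)
    conv <- fixture_conversion(p$kvp, p$bowtie)
    suppressWarnings(
      protocol_organ_doses(p, pp$phantom, pp$masks, factor = conv$factor,
                           n_photons = n_photons, n_batches = n_batches,
                           seed = seed))
  })
}

# independent type-7 quantile oracle (sort + linear interpolation)
oracle_quantile75 <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n == 1) return(s)
  h <- (n - 1) * 0.75 + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
}
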