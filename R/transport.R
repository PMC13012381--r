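# R-side interface to the Monte Carlo transport engine.

.N_PSI_BINS <- 48   # fan-angle discretization of the bowtie-filtered source

# Precompute the per-fan-bin bowtie-attenuated energy CDFs and
# transmitted weights for the sampling kernel.
.source_tables <- function(spectrum, geometry, bowtie) {
  validate_spectrum(spectrum)
  stopifnot(inherits(geometry, "beam_geometry"),
            inherits(bowtie, "bowtie_profile"))
  if (geometry$u_max_cm <= geometry$u_min_cm || geometry$v_half_cm <= 0)
    stop("zero beam aperture")
  u <- geometry$u_min_cm +
    (seq_len(.N_PSI_BINS) - 0.5) *
    (geometry$u_max_cm - geometry$u_min_cm) / .N_PSI_BINS
  psi_deg <- atan(u / geometry$sid_cm) * 180 / pi
  t_mm <- suppressWarnings(bowtie_thickness(bowtie, psi_deg))
  mu_al <- material_mu("aluminum", spectrum$energy_keV) *
    material_density("aluminum")
  f0 <- spectrum$fluence
  cdf <- matrix(0, length(f0), .N_PSI_BINS)
  w <- numeric(.N_PSI_BINS)
  for (j in seq_len(.N_PSI_BINS)) {
    fa <- f0 * exp(-mu_al * t_mm[j] / 10)
    w[j] <- sum(fa) / sum(f0)
    cdf[, j] <- cumsum(fa) / sum(fa)
  }
  list(spec_e = spectrum$energy_keV, cdf = cdf, psi_w = w)
}

.transport_tables <- function(phantom) {
  ta <- .phantom_transport_arrays(phantom)
  xt <- cross_section_table(ta$material_names)
  maxden <- vapply(seq_along(ta$material_names), function(m) {
    sel <- ta$material == m
    if (any(sel)) max(ta$density[sel]) else 0
  }, numeric(1))
  mu_maj <- apply(sweep(xt$mu, 2, maxden, `*`), 1, max)
  list(arrays = ta, xs = xt, mu_majorant = mu_maj)
}

#' Simulate the CBCT dose distribution in a voxel phantom
#'
#' Transports photons from the rotating CBCT source model through the
#' phantom by Woodcock tracking and scores per-voxel absorbed dose under
#' the collision-kerma approximation (secondary electrons deposit at the
#' interaction site; their CSDA range is sub-voxel at these energies).
#' Each photon samples a projection angle uniformly from the schedule, a
#' position uniformly over the field rectangle at the isocentre plane,
#' and an energy from the source spectrum attenuated by the bowtie filter
#' at its fan angle (the bowtie also down-weights the photon by its
#' transmitted fluence fraction).  Doses are scored in keV/g per
#' simulated source photon and later given an absolute scale by
#' [normalize_to_protocol()].
#'
#' @param phantom A `voxel_phantom`.
#' @param geometry A `beam_geometry` from [derive_geometry()] or
#'   [conversion_geometry()].
#' @param spectrum An `energy_spectrum`.
#' @param bowtie A `bowtie_profile` (default `"none"`).
#' @param masks Optional `organ_masks`; enables per-batch organ scoring
#'   for bootstrap uncertainty.
#' @param n_photons Number of source photons (>= `n_batches`, or 0 for an
#'   empty all-zero run).
#' @param n_batches Number of statistically independent batches (>= 2).
#' @param seed Integer seed; results are reproducible for a fixed seed
#'   and batch count.
#' @param rayleigh If `FALSE`, coherent scattering is treated as forward
#'   pass-through instead of Thomson-law deflection.
#' @return A `dose_grid`: per-voxel dose `grid` (keV/g per photon),
#'   per-batch per-organ mean doses `batch_organ`, per-batch emitted and
#'   deposited energy, and the grid lattice description.
#' @export
simulate_dose <- function(phantom, geometry, spectrum,
                          bowtie = bowtie_profile("none"), masks = NULL,
                          n_photons = 2e6, n_batches = 50, seed = 1,
                          rayleigh = TRUE) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  if (n_batches < 2) stop("need at least 2 batches")
  if (n_photons > 0 && n_photons < n_batches)
    stop("n_photons must be at least n_batches")
  dm <- dim(phantom$hu)
  if (!is.null(masks)) {
    stopifnot(inherits(masks, "organ_masks"))
    if (!identical(dim(masks$labels), dm) ||
        !isTRUE(all.equal(masks$spacing_mm, phantom$spacing_mm)))
      stop("phantom and masks are on different lattices")
    labels <- masks$labels
    organs <- names(masks$organs)
    counts <- vapply(masks$organs,
                     function(l) sum(labels == l), numeric(1))
  } else {
    labels <- integer(0)
    organs <- character(0)
    counts <- numeric(0)
  }
  tt <- .transport_tables(phantom)
  st <- .source_tables(spectrum, geometry, bowtie)
  res <- cpp_simulate_dose(
    as.numeric(tt$arrays$density), as.integer(tt$arrays$material),
    as.integer(dm), phantom$spacing_mm / 10, phantom$origin_mm / 10,
    tt$xs$mu, tt$xs$cum_photo, tt$xs$cum_compton,
    tt$xs$energy_keV[1], tt$mu_majorant,
    st$spec_e, st$cdf, st$psi_w, geometry$sid_cm,
    geometry$projection_angles_deg * pi / 180,
    geometry$u_min_cm, geometry$u_max_cm, geometry$v_half_cm,
    as.integer(labels), length(organs), counts,
    n_photons, as.integer(n_batches), as.integer(seed), 5.0, rayleigh)
  # engine scores totals; report per simulated source photon
  div <- max(n_photons, 1)
  bo <- res$batch_organ / div
  if (length(organs)) colnames(bo) <- organs
  structure(list(
    grid = array(res$dose / div, dm),
    batch_organ = if (length(organs)) bo else NULL,
    emitted_keV = res$emitted_keV,
    deposited_keV = res$deposited_keV,
    n_photons = n_photons, n_batches = n_batches, seed = seed,
    spacing_mm = phantom$spacing_mm, origin_mm = phantom$origin_mm,
    unit = "keV/g per photon"
  ), class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %s voxels, %g photons in %d batches [%s]\n",
              paste(dim(x$grid), collapse = " x "), x$n_photons,
              x$n_batches, x$unit))
  invisible(x)
}

#' Sample Compton scattering events
#'
#' Joint samples of scattered photon energy and scattering angle from
#' the Klein-Nishina differential cross-section with Compton kinematics.
#'
#' @param n Number of samples.
#' @param energy_keV Incident photon energy (5--150 keV).
#' @param seed Integer seed.
#' @return Matrix with columns `scattered_keV` and `cos_theta`.
#' @export
sample_compton <- function(n, energy_keV, seed = 1) {
  stopifnot(energy_keV >= 5, energy_keV <= 150, n >= 1)
  cpp_sample_compton(as.integer(n), energy_keV, as.integer(seed))
}

#' Score air kerma free-in-air at a point
#'
#' Fluence x energy x (mu_en/rho)_air estimator on a small tally disc
#' perpendicular to the central beam axis, with no phantom in the beam.
#'
#' @param geometry A `beam_geometry`.
#' @param spectrum An `energy_spectrum`.
#' @param bowtie A `bowtie_profile`.
#' @param point_mm Scoring point in room coordinates (mm); default the
#'   isocentre.
#' @param n_photons,seed Monte Carlo sampling parameters.
#' @param tally_radius_mm Radius of the scoring disc.
#' @return Air kerma in keV/g per source photon.
#' @export
score_air_kerma_free_in_air <- function(geometry, spectrum,
                                        bowtie = bowtie_profile("none"),
                                        point_mm = c(0, 0, 0),
                                        n_photons = 2e6, seed = 1,
                                        tally_radius_mm = 10) {
  st <- .source_tables(spectrum, geometry, bowtie)
  # the point must sit inside the beam: check against the aperture at its
  # plane for the first projection
  g <- geometry$projection_angles_deg[1] * pi / 180
  p_cm <- point_mm / 10
  e_u <- c(cos(g), -sin(g), 0)
  ax <- c(-sin(g), -cos(g), 0)
  s_cm <- c(geometry$sid_cm * sin(g), geometry$sid_cm * cos(g), 0)
  d_axis <- sum((p_cm - s_cm) * ax)
  if (d_axis <= 0) stop("point is behind the source")
  scale <- d_axis / geometry$sid_cm
  u_p <- sum(p_cm * e_u) / scale
  v_p <- p_cm[3] / scale
  if (u_p < geometry$u_min_cm - 1e-9 || u_p > geometry$u_max_cm + 1e-9 ||
      abs(v_p) > geometry$v_half_cm + 1e-9)
    stop("point is outside the beam aperture")
  muen_air <- material_muen("air", 5:150)
  cpp_air_kerma(st$spec_e, st$cdf, st$psi_w, geometry$sid_cm,
                geometry$projection_angles_deg * pi / 180,
                geometry$u_min_cm, geometry$u_max_cm, geometry$v_half_cm,
                p_cm, tally_radius_mm / 10, muen_air, 5,
                n_photons, as.integer(seed))
}

#' Narrow-beam transmission through a phantom
#'
#' Fires a monoenergetic pencil beam through the voxel grid and returns
#' the fraction of photons that cross without any real interaction; a
#' validation surface for the Woodcock tracker against the Beer-Lambert
#' closed form.
#'
#' @param phantom A `voxel_phantom`.
#' @param energy_keV Beam energy.
#' @param source_mm Source position (room coordinates, mm).
#' @param direction Beam direction vector.
#' @param n_photons,seed Monte Carlo parameters.
#' @return Transmitted fraction.
#' @export
transmission_fraction <- function(phantom, energy_keV,
                                  source_mm = c(0, 400, 0),
                                  direction = c(0, -1, 0),
                                  n_photons = 1e5, seed = 1) {
  tt <- .transport_tables(phantom)
  cpp_transmission(as.numeric(tt$arrays$density),
                   as.integer(tt$arrays$material),
                   as.integer(dim(phantom$hu)), phantom$spacing_mm / 10,
                   phantom$origin_mm / 10, tt$xs$mu, tt$xs$energy_keV[1],
                   tt$mu_majorant, energy_keV, source_mm / 10, direction,
                   n_photons, as.integer(seed))
}
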