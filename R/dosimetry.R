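# Absolute-dose chain: CTDI_w, CTDI_w -> air-kerma conversion,
# normalization of simulated grids to the printed CTDI_w, organ and ROI
# mean doses, bootstrap uncertainty, red-bone-marrow conversion, and the
# quadrature uncertainty budget.

# piecewise-linear integral of profile (z, d) over [a, b]
.trapz_interval <- function(z, d, a, b) {
  if (min(z) > a || max(z) < b)
    stop("integration range [", a, ", ", b, "] mm exceeds the profile")
  zz <- sort(unique(c(a, b, z[z > a & z < b])))
  dd <- stats::approx(z, d, xout = zz)$y
  sum(diff(zz) * (utils::head(dd, -1) + utils::tail(dd, -1)) / 2)
}

#' Compute CTDI_100 and CTDI_w from a simulated dose grid
#'
#' For each probe axis the dose profile D(z) is averaged transaxially
#' over a pencil-chamber-sized column (radius `probe_radius_mm`), then
#' CTDI_100 = (1/collimation) x integral of D(z) over z in \[-50, 50\] mm
#' (trapezoid rule on the voxel profile with linear interpolation at the
#' half-voxel edges).  CTDI_w combines centre and periphery with the
#' standard 1/3 + 2/3 weighting.
#'
#' @param grid A `dose_grid` over a CTDI phantom (any dose unit).
#' @param probes_mm Probe axis positions, as returned by
#'   [make_ctdi_phantom()] (first row the centre probe).
#' @param collimation_cm Total beam collimation at the isocentre, cm.
#' @param mas Optional tube loading, enables the `ctdiw_per_100mas`
#'   normalization field.
#' @param probe_radius_mm Averaging radius around each probe axis.
#' @return A `ctdi_result`: `ctdi100_centre`, `ctdi100_periphery_mean`,
#'   `ctdiw`, per-probe values, and (if `mas` given) `ctdiw_per_100mas`,
#'   all in the unit of `grid`.
#' @export
compute_ctdiw <- function(grid, probes_mm, collimation_cm, mas = NULL,
                          probe_radius_mm = 5) {
  stopifnot(inherits(grid, "dose_grid"))
  dm <- dim(grid$grid)
  cx <- grid$origin_mm[1] + (seq_len(dm[1]) - 0.5) * grid$spacing_mm[1]
  cy <- grid$origin_mm[2] + (seq_len(dm[2]) - 0.5) * grid$spacing_mm[2]
  cz <- grid$origin_mm[3] + (seq_len(dm[3]) - 0.5) * grid$spacing_mm[3]
  ctdi100 <- numeric(nrow(probes_mm))
  for (p in seq_len(nrow(probes_mm))) {
    sel <- outer((cx - probes_mm[p, 1])^2, (cy - probes_mm[p, 2])^2, "+") <=
      probe_radius_mm^2
    if (!any(sel)) stop("probe ", p, " does not intersect the grid")
    profile <- apply(grid$grid, 3, function(sl) mean(sl[sel]))
    ctdi100[p] <- .trapz_interval(cz, profile, -50, 50) /
      (collimation_cm * 10)
  }
  names(ctdi100) <- rownames(probes_mm)
  res <- list(ctdi100_centre = unname(ctdi100[1]),
              ctdi100_periphery_mean = mean(ctdi100[-1]),
              ctdiw = unname(ctdi100[1]) / 3 + 2 * mean(ctdi100[-1]) / 3,
              ctdi100 = ctdi100, collimation_cm = collimation_cm)
  if (!is.null(mas)) res$ctdiw_per_100mas <- res$ctdiw / mas * 100
  structure(res, class = "ctdi_result")
}

#' CTDI_w to air-kerma conversion factor
#'
#' Runs the fixed conversion setup -- 32 cm CTDI phantom, full-fan beam
#' with 16 degree total fan angle, 10 cm collimation, full rotation --
#' once with the phantom (scoring CTDI_w) and once free-in-air (scoring
#' air kerma at the isocentre), both per source photon, and returns their
#' ratio K_a / CTDI_w.  The factor is independent of the simulated photon
#' count and of the tube loading; it depends only on the spectrum and
#' bowtie filter.
#'
#' @param spectrum An `energy_spectrum`.
#' @param bowtie A `bowtie_profile`.
#' @param n_photons,n_batches,seed Monte Carlo parameters.
#' @param spacing_mm Voxel spacing of the CTDI phantom.
#' @return Dimensionless factor with attributes `ctdiw_per_photon` and
#'   `ka_per_photon` (keV/g per source photon).
#' @export
ctdiw_to_ka_factor <- function(spectrum, bowtie = bowtie_profile("none"),
                               n_photons = 2e6, n_batches = 10, seed = 1,
                               spacing_mm = 2.5) {
  ct <- make_ctdi_phantom(32, spacing_mm = spacing_mm)
  geom <- conversion_geometry()
  g <- simulate_dose(ct$phantom, geom, spectrum, bowtie,
                     n_photons = n_photons, n_batches = n_batches,
                     seed = seed)
  ctdi <- compute_ctdiw(g, ct$probes_mm, collimation_cm = 10)
  ka <- score_air_kerma_free_in_air(geom, spectrum, bowtie,
                                    n_photons = ceiling(n_photons / 2),
                                    seed = seed + 1)
  if (ctdi$ctdiw <= 0) stop("simulated CTDI_w is zero")
  structure(ka / ctdi$ctdiw, ctdiw_per_photon = ctdi$ctdiw,
            ka_per_photon = ka)
}

#' Normalize a simulated dose grid to a protocol's printed CTDI_w
#'
#' Fixes the absolute scale of a per-source-photon dose grid so that the
#' air kerma free-in-air at the isocentre equals the protocol's printed
#' CTDI_w times the conversion factor.  All voxel doses are multiplied by
#' the single constant (factor x CTDI_w) / K_a,sim.
#'
#' @param grid A `dose_grid` simulated under the protocol's geometry and
#'   spectrum (keV/g per photon).
#' @param protocol The `protocol` (its `ctdiw_mGy` anchors the scale).
#' @param factor Conversion factor from [ctdiw_to_ka_factor()].
#' @param ka_per_photon Simulated air kerma free-in-air at the isocentre
#'   under the same source model as `grid`, keV/g per photon (from
#'   [score_air_kerma_free_in_air()]).
#' @return The `dose_grid` rescaled to mGy per imaged fraction.
#' @export
normalize_to_protocol <- function(grid, protocol, factor, ka_per_photon) {
  stopifnot(inherits(grid, "dose_grid"))
  if (!inherits(protocol, "protocol")) protocol <- as_protocol(protocol)
  if (!is.finite(ka_per_photon) || ka_per_photon <= 0)
    stop("simulated air kerma must be positive")
  scale <- as.numeric(factor) * protocol$ctdiw_mGy / ka_per_photon
  grid$grid <- grid$grid * scale
  if (!is.null(grid$batch_organ)) grid$batch_organ <- grid$batch_organ * scale
  grid$unit <- "mGy per fraction"
  grid$scale_to_mGy <- scale
  grid
}

#' Bootstrap standard uncertainty of batch means
#'
#' Resamples batches with replacement and returns the standard deviation
#' of the resampled means, per column.  Deterministic for a fixed seed.
#'
#' @param batch_values Numeric matrix (batches x quantities) or vector.
#' @param n_resamples Number of bootstrap resamples.
#' @param seed Integer seed.
#' @return Named numeric vector of standard uncertainties of the mean.
#' @export
bootstrap_uncertainty <- function(batch_values, n_resamples = 1000,
                                  seed = 1) {
  if (is.vector(batch_values)) batch_values <- cbind(value = batch_values)
  n <- nrow(batch_values)
  if (n < 2) stop("need at least 2 batches for bootstrap uncertainty")
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_resamples, replace = TRUE),
                n_resamples, n)
  means <- apply(batch_values, 2, function(x) {
    rowMeans(matrix(x[idx], n_resamples, n))
  })
  apply(means, 2, stats::sd)
}

#' Mean organ doses with bootstrap uncertainty
#'
#' Arithmetic mean of the dose grid over each organ mask; the standard
#' uncertainty is the bootstrap spread of the per-batch organ
#' contributions when the grid carries them.
#'
#' @param grid A `dose_grid` (absolute, mGy, for reportable values).
#' @param masks An `organ_masks` set on the same lattice.
#' @param n_resamples,seed Bootstrap parameters.
#' @return An `organ_dose_report` data frame: `organ`, `dose`,
#'   `uncertainty`, `n_voxels`.
#' @export
organ_mean_doses <- function(grid, masks, n_resamples = 1000, seed = 1) {
  stopifnot(inherits(grid, "dose_grid"), inherits(masks, "organ_masks"))
  if (!identical(dim(masks$labels), dim(grid$grid)))
    stop("grid and masks are on different lattices")
  organs <- names(masks$organs)
  dose <- unc <- nv <- numeric(length(organs))
  for (i in seq_along(organs)) {
    idx <- organ_indices(masks, organs[i])
    if (!length(idx)) stop("empty mask for organ '", organs[i], "'")
    nv[i] <- length(idx)
    dose[i] <- mean(grid$grid[idx])
  }
  if (!is.null(grid$batch_organ)) {
    bo <- grid$batch_organ[, organs, drop = FALSE]
    unc <- bootstrap_uncertainty(bo, n_resamples, seed) * grid$n_batches
  } else {
    unc <- rep(NA_real_, length(organs))
  }
  structure(data.frame(organ = organs, dose = dose, uncertainty = unc,
                       n_voxels = nv, stringsAsFactors = FALSE),
            unit = grid$unit, class = c("organ_dose_report", "data.frame"))
}

#' Mean dose in a geometric region of interest
#'
#' @param grid A `dose_grid`.
#' @param roi Either `list(type = "sphere", center_mm, radius_mm)` or
#'   `list(type = "box", lower_mm, upper_mm)`, in room coordinates.
#' @return Mean dose over the voxels whose centres fall in the ROI.
#' @export
roi_mean_dose <- function(grid, roi) {
  stopifnot(inherits(grid, "dose_grid"))
  dm <- dim(grid$grid)
  cx <- grid$origin_mm[1] + (seq_len(dm[1]) - 0.5) * grid$spacing_mm[1]
  cy <- grid$origin_mm[2] + (seq_len(dm[2]) - 0.5) * grid$spacing_mm[2]
  cz <- grid$origin_mm[3] + (seq_len(dm[3]) - 0.5) * grid$spacing_mm[3]
  X <- array(rep(cx, times = dm[2] * dm[3]), dm)
  Y <- array(rep(rep(cy, each = dm[1]), times = dm[3]), dm)
  Z <- array(rep(cz, each = dm[1] * dm[2]), dm)
  sel <- switch(roi$type,
    sphere = (X - roi$center_mm[1])^2 + (Y - roi$center_mm[2])^2 +
      (Z - roi$center_mm[3])^2 <= roi$radius_mm^2,
    box = X >= roi$lower_mm[1] & X <= roi$upper_mm[1] &
      Y >= roi$lower_mm[2] & Y <= roi$upper_mm[2] &
      Z >= roi$lower_mm[3] & Z <= roi$upper_mm[3],
    stop("roi$type must be 'sphere' or 'box'"))
  if (!any(sel)) stop("ROI does not intersect the dose grid")
  mean(grid$grid[sel])
}

#' Combine independent relative uncertainties in quadrature
#'
#' @param components Non-negative relative uncertainties in percent.
#' @return Square root of the sum of squares, percent.
#' @export
combine_uncertainties <- function(components) {
  if (any(components < 0)) stop("uncertainty components must be >= 0")
  sqrt(sum(components^2))
}

# --- Red bone marrow -------------------------------------------------------

#' Load the red-bone-marrow MEAC/DEF factor table
#'
#' Tabulated ratios of RBM to spongiosa mass energy-absorption
#' coefficients and dose enhancement factors per skeletal site (femora,
#' pelvis, sacrum) versus photon energy; interpolated log-linearly in
#' energy.  The shipped table is a synthetic reconstruction (see the file
#' header in `extdata/rbm_meac_factors_synthetic.csv`).
#'
#' @param path Optional path to an alternative table with columns
#'   `site`, `energy_keV`, `meac_ratio`, `def`.
#' @return An `rbm_factors` object (list per site).
#' @export
rbm_factors <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "rbm_meac_factors_synthetic.csv",
                        package = "cbctdose", mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#")
  stopifnot(all(c("site", "energy_keV", "meac_ratio", "def") %in%
                  names(tab)), all(tab$meac_ratio > 0), all(tab$def > 0))
  structure(split(tab[c("energy_keV", "meac_ratio", "def")], tab$site),
            class = "rbm_factors")
}

.rbm_interp <- function(tab, what, energy_keV) {
  e <- pmin(pmax(energy_keV, min(tab$energy_keV)), max(tab$energy_keV))
  stats::approx(log(tab$energy_keV), tab[[what]], xout = log(e))$y
}

#' Red-bone-marrow dose by the three-parameter MEAC method
#'
#' Converts the mean absorbed dose in a site's spongiosa to the red
#' bone marrow dose: D_RBM = D_spongiosa x <ratio>_w x <DEF>_w, where the
#' spectrum-weighted averages use the initial tube spectrum as the
#' estimate of the photon fluence at the marrow site, weighted per bin by
#' its collision-kerma contribution in spongiosa (fluence x energy x
#' (mu_en/rho)_spongiosa).
#'
#' @param spongiosa_dose Mean spongiosa absorbed dose (mGy).
#' @param spectrum The initial tube `energy_spectrum` of the protocol.
#' @param site `"femora"`, `"pelvis"` or `"sacrum"`.
#' @param factors An `rbm_factors` table.
#' @return RBM dose in the unit of `spongiosa_dose`, with attributes
#'   `meac_ratio_w` and `def_w` (the spectrum-weighted averages).
#' @export
rbm_dose <- function(spongiosa_dose, spectrum, site,
                     factors = rbm_factors()) {
  validate_spectrum(spectrum)
  if (!site %in% names(factors))
    stop("site '", site, "' is not tabulated; have: ",
         paste(names(factors), collapse = ", "))
  tab <- factors[[site]]
  w <- spectrum$fluence * spectrum$energy_keV *
    material_muen("spongiosa", spectrum$energy_keV)
  ratio_w <- sum(w * .rbm_interp(tab, "meac_ratio", spectrum$energy_keV)) /
    sum(w)
  def_w <- sum(w * .rbm_interp(tab, "def", spectrum$energy_keV)) / sum(w)
  structure(spongiosa_dose * ratio_w * def_w,
            meac_ratio_w = ratio_w, def_w = def_w)
}

# --- End-to-end pipeline ---------------------------------------------------

#' Simulate absolute organ doses for one protocol
#'
#' Full chain for a registry protocol: tube spectrum, beam geometry,
#' Monte Carlo dose simulation on the pelvis phantom, free-in-air kerma
#' under the same source model, CTDI_w normalization, organ mean doses,
#' and RBM conversion for the three skeletal sites.
#'
#' @param protocol A `protocol` (or registry row / hospital code string).
#' @param phantom,masks Pelvis phantom and organ masks from
#'   [make_pelvis_phantom()].
#' @param factor Conversion factor from [ctdiw_to_ka_factor()] for this
#'   protocol's spectrum and bowtie; computed on the fly if `NULL`.
#' @param n_photons,n_batches,seed Monte Carlo parameters.
#' @param site Registry site used when `protocol` is a hospital code.
#' @return A data frame (one row per organ, including `femora_rbm`,
#'   `pelvis_rbm`, `sacrum_rbm`) with doses in mGy per imaged fraction.
#' @export
protocol_organ_doses <- function(protocol, phantom, masks, factor = NULL,
                                 n_photons = 2e6, n_batches = 50, seed = 1,
                                 site = NULL) {
  if (is.character(protocol)) protocol <- get_protocol(protocol, site)
  if (!inherits(protocol, "protocol")) protocol <- as_protocol(protocol)
  spec <- generate_spectrum(protocol$kvp)
  geom <- derive_geometry(protocol)
  bt <- bowtie_profile(protocol$bowtie)
  if (is.null(factor))
    factor <- ctdiw_to_ka_factor(spec, bt, n_photons = n_photons,
                                 seed = seed + 1000)
  g <- simulate_dose(phantom, geom, spec, bt, masks = masks,
                     n_photons = n_photons, n_batches = n_batches,
                     seed = seed)
  ka <- score_air_kerma_free_in_air(geom, spec, bt,
                                    n_photons = ceiling(n_photons / 2),
                                    seed = seed + 1)
  g <- normalize_to_protocol(g, protocol, factor, ka)
  rep_ <- organ_mean_doses(g, masks, seed = seed)
  fac <- rbm_factors()
  for (s in c("femora", "pelvis", "sacrum")) {
    row <- rep_[rep_$organ == paste0(s, "_spongiosa"), ]
    d <- rbm_dose(row$dose, spec, s, fac)
    rep_ <- rbind(rep_, data.frame(
      organ = paste0(s, "_rbm"), dose = as.numeric(d),
      uncertainty = row$uncertainty * as.numeric(d) / row$dose,
      n_voxels = row$n_voxels))
  }
  rep_$protocol <- protocol$hospital
  attr(rep_, "unit") <- "mGy per fraction"
  rep_
}
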