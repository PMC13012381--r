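# Embedded photon interaction data for the kilovoltage energy range.
#
# Mass attenuation (mu/rho) and mass energy-absorption (mu_en/rho)
# coefficients, cm^2/g, tabulated on a sparse energy grid and
# log-log-interpolated onto a 1 keV working grid.  Values are taken from
# the NIST XCOM/XAAMDI compilations at the printed table nodes; entries
# below 10 keV for high-Z or bone-like media are smooth extrapolations
# (photons there are scarce after inherent filtration and carry little
# dose).  Spongiosa (trabecular bone) is modelled as a mass-weighted
# mixture of cortical bone and soft tissue.

.xs_energy <- c(5, 6, 8, 10, 15, 20, 30, 40, 50, 60, 80, 100, 150)

.xs_data <- local({
  water_mu   <- c(42.58, 24.64, 10.37, 5.329, 1.673, 0.8096, 0.3756, 0.2683,
                  0.2269, 0.2059, 0.1837, 0.1707, 0.1505)
  water_muen <- c(41.73, 24.07, 10.06, 4.944, 1.374, 0.5503, 0.1557, 0.06947,
                  0.04223, 0.03190, 0.02597, 0.02546, 0.02764)
  air_mu     <- c(40.27, 23.41, 9.921, 5.120, 1.614, 0.7779, 0.3538, 0.2485,
                  0.2080, 0.1875, 0.1662, 0.1541, 0.1356)
  air_muen   <- c(39.31, 22.70, 9.446, 4.742, 1.334, 0.5389, 0.1537, 0.06833,
                  0.04098, 0.03041, 0.02407, 0.02325, 0.02496)
  al_mu      <- c(193.4, 115.3, 50.33, 26.23, 7.955, 3.441, 1.128, 0.5685,
                  0.3681, 0.2778, 0.2018, 0.1704, 0.1378)
  al_muen    <- c(184.6, 110.0, 48.13, 25.43, 7.487, 3.094, 0.8778, 0.3601,
                  0.1840, 0.1099, 0.05511, 0.03794, 0.02827)
  pmma_mu    <- c(27.00, 15.70, 6.640, 3.357, 1.101, 0.5714, 0.3032, 0.2350,
                  0.2074, 0.1924, 0.1751, 0.1641, 0.1456)
  pmma_muen  <- c(26.40, 15.30, 6.400, 3.026, 0.9663, 0.3328, 0.09645, 0.04599,
                  0.03067, 0.02530, 0.02302, 0.02368, 0.02657)
  tiss_mu    <- c(43.10, 24.90, 10.55, 5.367, 1.693, 0.8205, 0.3783, 0.2685,
                  0.2262, 0.2048, 0.1823, 0.1693, 0.1492)
  tiss_muen  <- c(42.30, 24.40, 10.26, 4.987, 1.402, 0.5663, 0.1610, 0.07192,
                  0.04349, 0.03258, 0.02615, 0.02544, 0.02745)
  bone_mu    <- c(190.0, 115.0, 52.00, 28.51, 9.032, 4.001, 1.331, 0.6655,
                  0.4242, 0.3148, 0.2229, 0.1855, 0.1480)
  bone_muen  <- c(185.0, 111.0, 50.00, 26.80, 8.388, 3.601, 1.070, 0.4507,
                  0.2336, 0.1400, 0.06896, 0.04585, 0.03183)
  spong_frac <- 0.35   # cortical-bone mass fraction in the spongiosa mixture
  list(
    water = list(mu = water_mu, muen = water_muen, density = 1.000,
                 z_over_a = 0.5551),
    air = list(mu = air_mu, muen = air_muen, density = 0.0012,
               z_over_a = 0.4992),
    aluminum = list(mu = al_mu, muen = al_muen, density = 2.699,
                    z_over_a = 0.4818),
    pmma = list(mu = pmma_mu, muen = pmma_muen, density = 1.190,
                z_over_a = 0.5394),
    soft_tissue = list(mu = tiss_mu, muen = tiss_muen, density = 1.060,
                       z_over_a = 0.5500),
    lung = list(mu = tiss_mu, muen = tiss_muen, density = 0.260,
                z_over_a = 0.5500),
    cortical_bone = list(mu = bone_mu, muen = bone_muen, density = 1.920,
                         z_over_a = 0.5148),
    spongiosa = list(mu = spong_frac * bone_mu + (1 - spong_frac) * tiss_mu,
                     muen = spong_frac * bone_muen + (1 - spong_frac) * tiss_muen,
                     density = 1.180,
                     z_over_a = spong_frac * 0.5148 + (1 - spong_frac) * 0.5500)
  )
})

# Tungsten total attenuation, used only for anode self-filtration in the
# spectrum model; L- and K-edge structure represented coarsely.
.w_energy <- c(5, 6, 8, 10, 10.25, 12, 15, 20, 30, 40, 50, 60, 69.4, 69.6,
               80, 100, 120, 150)
.w_mu <- c(571, 357, 168, 96.9, 290, 200, 139, 65.73, 22.73, 10.67, 5.949,
           3.713, 2.575, 11.0, 7.810, 4.438, 2.766, 1.581)

#' Materials known to the embedded cross-section library
#'
#' @return Character vector of material names accepted by
#'   [material_mu()], [material_muen()] and [attenuate_spectrum()].
#' @export
material_names <- function() names(.xs_data)

.material_lookup <- function(material) {
  material <- tolower(material)
  material <- switch(material,
                     "al" = "aluminum", "aluminium" = "aluminum",
                     "tissue" = "soft_tissue", "bone" = "cortical_bone",
                     material)
  if (!material %in% names(.xs_data))
    stop("unknown material '", material, "'; see material_names()",
         call. = FALSE)
  material
}

.loglog_interp <- function(xs, ys, x) {
  x <- pmin(pmax(x, min(xs)), max(xs))
  exp(stats::approx(log(xs), log(ys), xout = log(x))$y)
}

#' Mass attenuation coefficient of an embedded material
#'
#' Total mass attenuation coefficient \eqn{\mu/\rho} (coherent scattering
#' included), log-log interpolated between table nodes; energies outside
#' the tabulated 5--150 keV range are clamped.
#'
#' @param material Material name (see [material_names()]; `"Al"` and
#'   `"aluminium"` are accepted aliases).
#' @param energy_keV Photon energies in keV.
#' @return Numeric vector of \eqn{\mu/\rho} in cm^2/g.
#' @export
material_mu <- function(material, energy_keV) {
  m <- .xs_data[[.material_lookup(material)]]
  .loglog_interp(.xs_energy, m$mu, energy_keV)
}

#' Mass energy-absorption coefficient of an embedded material
#'
#' @inheritParams material_mu
#' @return Numeric vector of \eqn{\mu_{en}/\rho} in cm^2/g.
#' @export
material_muen <- function(material, energy_keV) {
  m <- .xs_data[[.material_lookup(material)]]
  .loglog_interp(.xs_energy, m$muen, energy_keV)
}

#' Nominal density of an embedded material
#'
#' @inheritParams material_mu
#' @return Density in g/cm^3.
#' @export
material_density <- function(material) {
  .xs_data[[.material_lookup(material)]]$density
}

.w_mu_interp <- function(energy_keV) {
  .loglog_interp(.w_energy, .w_mu, energy_keV)
}

# Klein-Nishina total cross section per electron, cm^2.
.kn_total <- function(energy_keV) {
  a <- energy_keV / 510.999
  r0 <- 2.8179403e-13 # classical electron radius, cm
  term <- (1 + a) / a^2 * (2 * (1 + a) / (1 + 2 * a) - log(1 + 2 * a) / a) +
    log(1 + 2 * a) / (2 * a) - (1 + 3 * a) / (1 + 2 * a)^2
  2 * pi * r0^2 * term
}

# Mean fraction of the photon energy transferred to the Compton electron
# under the Klein-Nishina distribution (numeric quadrature over the
# scattering angle).
.kn_transfer_fraction <- function(energy_keV) {
  vapply(energy_keV, function(e) {
    a <- e / 510.999
    cth <- seq(-1, 1, length.out = 2001)
    x <- 1 / (1 + a * (1 - cth))                 # E'/E
    dcs <- x^2 * (x + 1 / x - (1 - cth^2))       # KN, arbitrary norm
    sum(dcs * (1 - x)) / sum(dcs)
  }, numeric(1))
}

# Interaction-type partition of the total attenuation coefficient on a
# 1 keV working grid.  Incoherent scattering follows Klein-Nishina times
# the electron density (free-electron approximation); photoelectric
# absorption is anchored on the mass energy-absorption tables,
# tau ~ mu_en - mu_inc * f_T with f_T the Klein-Nishina energy-transfer
# fraction (radiative losses are negligible below 150 keV); coherent
# scattering is the non-negative remainder, so the three channels sum to
# the NIST total by construction.
.material_partition <- function(material, egrid) {
  key <- .material_lookup(material)
  m <- .xs_data[[key]]
  mu_tot <- material_mu(key, egrid)
  muen <- material_muen(key, egrid)
  n_e <- m$z_over_a * 6.02214076e23               # electrons per gram
  mu_inc <- pmin(n_e * .kn_total(egrid), 0.995 * mu_tot)
  f_t <- .kn_transfer_fraction(egrid)
  mu_pho <- pmax(muen - mu_inc * f_t, 1e-8)
  mu_pho <- pmin(mu_pho, mu_tot - mu_inc)
  mu_coh <- pmax(mu_tot - mu_pho - mu_inc, 0)
  list(total = mu_tot, photoelectric = mu_pho, incoherent = mu_inc,
       coherent = mu_coh)
}

#' Cross-section table for the transport engine
#'
#' Builds, for a set of materials, total attenuation and per-interaction
#' partitions (photoelectric, incoherent/Compton, coherent/Rayleigh) plus
#' mass energy-absorption coefficients on a uniform 1 keV grid from 5 to
#' 150 keV.
#'
#' @param materials Character vector of material names.
#' @return Object of class `cross_section_table`: list with `energy_keV`
#'   and per-material matrices `mu`, `muen`, `cum_photo`, `cum_compton`
#'   (cumulative interaction fractions) with one column per material.
#' @export
cross_section_table <- function(materials) {
  materials <- vapply(materials, .material_lookup, character(1))
  egrid <- 5:150
  nm <- length(materials)
  mu <- muen <- cph <- cco <- matrix(0, length(egrid), nm,
                                     dimnames = list(NULL, materials))
  for (j in seq_len(nm)) {
    p <- .material_partition(materials[j], egrid)
    mu[, j] <- p$total
    muen[, j] <- material_muen(materials[j], egrid)
    cph[, j] <- p$photoelectric / p$total
    cco[, j] <- (p$photoelectric + p$incoherent) / p$total
  }
  structure(list(energy_keV = egrid, materials = materials, mu = mu,
                 muen = muen, cum_photo = cph, cum_compton = cco),
            class = "cross_section_table")
}
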