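# Kilovoltage X-ray tube spectra.
#
# A semi-empirical tungsten-anode model in the tradition of Birch &
# Marshall-type codes: a Kramers bremsstrahlung continuum, depth-dependent
# anode self-filtration via the Thomson-Whiddington electron penetration
# law, tungsten K characteristic lines above the 69.5 keV K edge, and
# Beer-Lambert inherent/added filtration.  The model is self-contained;
# its embedded physical data live in R/materials.R.

.TW_CONSTANT <- 7.6e5   # Thomson-Whiddington constant, keV^2 cm^2/g
.W_K_EDGE <- 69.525     # tungsten K edge, keV
.W_DENSITY <- 19.30     # g/cm^3 (not used directly; paths kept in g/cm^2)

new_energy_spectrum <- function(energy_keV, fluence, kvp, filtration = list()) {
  s <- structure(list(energy_keV = energy_keV, fluence = fluence, kvp = kvp,
                      filtration = filtration),
                 class = "energy_spectrum")
  validate_spectrum(s)
  s
}

validate_spectrum <- function(s) {
  stopifnot(inherits(s, "energy_spectrum"))
  e <- s$energy_keV
  f <- s$fluence
  if (length(e) != length(f)) stop("energy and fluence lengths differ")
  if (any(diff(e) <= 0)) stop("bin centers must be strictly increasing")
  if (length(e) > 1 && any(diff(e) > 1 + 1e-9))
    stop("bin width must be at most 1 keV")
  if (any(f < 0)) stop("fluence must be non-negative")
  if (!any(f > 0)) stop("spectrum has no fluence")
  if (any(e[f > 0] > s$kvp + 1e-9))
    stop("populated bins above the tube potential")
  if (min(e) > 5 + 1e-9 || max(e) < s$kvp - 1e-9)
    stop("bin grid must cover [5 keV, kvp]")
  invisible(s)
}

.normalize_filtration <- function(filtration) {
  if (is.null(filtration) || length(filtration) == 0) return(list())
  if (is.data.frame(filtration))
    filtration <- Map(list, filtration[[1]], as.numeric(filtration[[2]]))
  lapply(filtration, function(x) {
    mat <- .material_lookup(as.character(x[[1]]))
    th <- as.numeric(x[[2]])
    if (th < 0) stop("filtration thickness must be non-negative")
    list(material = mat, thickness_mm = th)
  })
}

#' Generate a kilovoltage X-ray tube spectrum
#'
#' Semi-empirical tungsten-anode model: Kramers continuum weighted by
#' anode self-filtration (Thomson-Whiddington effective production depth
#' divided by the sine of the anode angle), K characteristic lines for
#' tube potentials above the tungsten K edge, then Beer-Lambert
#' filtration.  Fluence is binned on a uniform 1 keV grid from 5 keV to
#' the tube potential.
#'
#' @param kvp Tube potential in kV (40--150).
#' @param anode_angle_deg Anode angle in degrees (default 14, typical for
#'   linac-mounted kV tubes).
#' @param filtration List of `list(material, thickness_mm)` pairs (or a
#'   two-column data frame); default 2.5 mm aluminum inherent filtration.
#' @return An `energy_spectrum`: bin centers `energy_keV`, relative
#'   `fluence` weights, `kvp`, and the applied `filtration`.
#' @examples
#' s <- generate_spectrum(120)
#' spectrum_stats(s)
#' @export
generate_spectrum <- function(kvp, anode_angle_deg = 14,
                              filtration = list(list("aluminum", 2.5))) {
  if (!is.finite(kvp) || kvp < 40 || kvp > 150)
    stop("kvp must lie in [40, 150]")
  filtration <- .normalize_filtration(filtration)
  energy <- seq(5, kvp, by = 1)
  if (energy[length(energy)] < kvp) energy <- c(energy, kvp)
  # Kramers fluence with anode self-filtration
  depth <- pmax(kvp^2 - energy^2, 0) / (2 * .TW_CONSTANT)   # g/cm^2
  path <- depth / sin(anode_angle_deg * pi / 180)
  fl <- pmax(kvp - energy, 0) / energy * exp(-.w_mu_interp(energy) * path)
  # K characteristic lines (Kalpha2, Kalpha1, Kbeta1, Kbeta2)
  if (kvp > .W_K_EDGE) {
    k_frac <- 0.09 * ((kvp - .W_K_EDGE) / (120 - .W_K_EDGE))^1.5
    line_e <- c(57.98, 59.32, 67.24, 69.10)
    line_w <- c(0.57, 1.00, 0.33, 0.08)
    line_w <- line_w / sum(line_w) * k_frac / (1 - k_frac) * sum(fl)
    for (i in seq_along(line_e)) {
      j <- which.min(abs(energy - line_e[i]))
      fl[j] <- fl[j] + line_w[i]
    }
  }
  s <- new_energy_spectrum(energy, fl / max(fl), kvp, filtration = list())
  for (f in filtration)
    s <- attenuate_spectrum(s, f$material, f$thickness_mm)
  s
}

#' Attenuate a spectrum through a slab of material
#'
#' Per-bin Beer-Lambert attenuation: fluence is multiplied by
#' \eqn{\exp(-\mu(E)\,t)} using the embedded attenuation data; the bin
#' grid is unchanged.
#'
#' @param s An `energy_spectrum`.
#' @param material Material name (see [material_names()]).
#' @param thickness_mm Slab thickness in mm (>= 0).
#' @param density Override density in g/cm^3 (default: nominal density of
#'   the material).
#' @return The attenuated `energy_spectrum`.
#' @export
attenuate_spectrum <- function(s, material, thickness_mm, density = NULL) {
  validate_spectrum(s)
  if (thickness_mm < 0) stop("thickness must be non-negative")
  material <- .material_lookup(material)
  if (is.null(density)) density <- material_density(material)
  mu <- material_mu(material, s$energy_keV) * density        # 1/cm
  fl <- s$fluence * exp(-mu * thickness_mm / 10)
  out <- s
  out$fluence <- fl
  out$filtration <- c(s$filtration,
                      list(list(material = material,
                                thickness_mm = thickness_mm)))
  out
}

.air_kerma_weight <- function(s) {
  # air collision kerma per unit total fluence, arbitrary units
  sum(s$fluence * s$energy_keV * material_muen("air", s$energy_keV))
}

#' Summary statistics of an energy spectrum
#'
#' @param s An `energy_spectrum`.
#' @return List with `mean_energy_keV` (fluence-weighted), the air-kerma
#'   weighting `air_kerma_per_fluence` (keV cm^2/g per photon), and the
#'   first half-value layer `hvl_mm_al` in mm of aluminum.
#' @export
spectrum_stats <- function(s) {
  validate_spectrum(s)
  if (sum(s$fluence) <= 0) stop("all-zero fluence")
  mean_e <- sum(s$fluence * s$energy_keV) / sum(s$fluence)
  k0 <- .air_kerma_weight(s)
  kerma_ratio <- function(t_mm) {
    .air_kerma_weight(attenuate_spectrum(s, "aluminum", t_mm)) / k0
  }
  hvl <- stats::uniroot(function(t) kerma_ratio(t) - 0.5,
                        interval = c(0, 40), tol = 1e-6)$root
  list(mean_energy_keV = mean_e,
       air_kerma_per_fluence = k0 / sum(s$fluence),
       hvl_mm_al = hvl)
}

#' Write a spectrum as two-column text
#'
#' @param s An `energy_spectrum`.
#' @param path Output path; columns are energy (keV) and relative fluence.
#' @export
write_spectrum <- function(s, path) {
  validate_spectrum(s)
  utils::write.table(data.frame(energy_keV = s$energy_keV,
                                fluence = s$fluence),
                     path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' Read a spectrum written by [write_spectrum()]
#'
#' @param path Input path.
#' @param kvp Tube potential of the stored spectrum; defaults to the
#'   highest populated bin.
#' @export
read_spectrum <- function(path, kvp = NULL) {
  d <- utils::read.table(path, header = TRUE)
  if (is.null(kvp)) kvp <- max(d[[1]][d[[2]] > 0])
  new_energy_spectrum(d[[1]], d[[2]], kvp)
}

#' @export
print.energy_spectrum <- function(x, ...) {
  st <- spectrum_stats(x)
  cat(sprintf("<energy_spectrum> %g kV, %d bins (%g-%g keV)\n",
              x$kvp, length(x$energy_keV), min(x$energy_keV),
              max(x$energy_keV)))
  cat(sprintf("  mean energy %.1f keV, HVL %.2f mm Al\n",
              st$mean_energy_keV, st$hvl_mm_al))
  invisible(x)
}
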