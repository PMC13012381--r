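# Voxel phantoms and synthetic survey data.
#
# Coordinate convention (fixed for all geometry in this package):
# right-handed room coordinates in mm, isocentre at the origin,
# x = patient left, y = anterior, z = cranio-caudal (superior positive).
# Voxels are cell-centred and 1-based; `origin_mm` is the position of the
# outer corner of voxel (1,1,1), so the centre of voxel (i,j,k) is
# origin + (c(i,j,k) - 0.5) * spacing.

.PHANTOM_MATERIALS <- c("air", "lung", "soft_tissue", "spongiosa",
                        "cortical_bone")

new_voxel_phantom <- function(hu, spacing_mm, origin_mm,
                              material = NULL, density = NULL,
                              material_names = .PHANTOM_MATERIALS) {
  stopifnot(length(dim(hu)) == 3, all(spacing_mm > 0),
            all(hu >= -1050 & hu <= 3000))
  structure(list(hu = hu, spacing_mm = spacing_mm, origin_mm = origin_mm,
                 material = material, density = density,
                 material_names = material_names),
            class = "voxel_phantom")
}

#' Voxel centre coordinates of a phantom axis
#' @param phantom A `voxel_phantom`.
#' @param axis 1, 2 or 3.
#' @return Numeric vector of voxel-centre coordinates in mm.
#' @export
voxel_centers <- function(phantom, axis) {
  n <- dim(phantom$hu)[axis]
  phantom$origin_mm[axis] + (seq_len(n) - 0.5) * phantom$spacing_mm[axis]
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$hu)
  cat(sprintf("<voxel_phantom> %d x %d x %d voxels, %.2g x %.2g x %.2g mm\n",
              d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2],
              x$spacing_mm[3]))
  invisible(x)
}

#' Map Hounsfield units to density and transport material
#'
#' Piecewise mapping, total over the clamped HU range and monotone in
#' density: HU <= -900 is air; (-900, -100] lung-density soft tissue with
#' a linear density ramp; (-100, +150] soft tissue, density 1 + HU/1000
#' (anchored at water, HU 0 = 1.00 g/cm^3); above +150 a bone mixture
#' with a linear ramp reaching cortical-bone density (1.92 g/cm^3) at
#' HU 1300; (150, 650] uses spongiosa (trabecular mixture) interaction
#' coefficients and higher values cortical bone.
#'
#' @param hu Numeric vector of Hounsfield units (clamped to
#'   \[-1050, 3000\]).
#' @return List with `density` (g/cm^3), `material_index` (into
#'   `material_names`), and `material_names`.
#' @export
hu_to_material <- function(hu) {
  hu <- pmin(pmax(hu, -1050), 3000)
  density <- numeric(length(hu))
  idx <- integer(length(hu))
  air <- hu <= -900
  lung <- hu > -900 & hu <= -100
  soft <- hu > -100 & hu <= 150
  spong <- hu > 150 & hu <= 650
  cort <- hu > 650
  density[air] <- 0.0012
  density[lung] <- 1 + hu[lung] / 1000
  density[soft] <- 1 + hu[soft] / 1000
  ramp <- function(h) 1.15 + (h - 150) * (1.92 - 1.15) / (1300 - 150)
  density[spong] <- ramp(hu[spong])
  density[cort] <- ramp(hu[cort])
  idx[air] <- 1L; idx[lung] <- 2L; idx[soft] <- 3L
  idx[spong] <- 4L; idx[cort] <- 5L
  list(density = density, material_index = idx,
       material_names = .PHANTOM_MATERIALS)
}

# Resolve explicit material/density arrays for transport, deriving them
# from HU when the phantom does not carry them.
.phantom_transport_arrays <- function(phantom) {
  if (!is.null(phantom$material) && !is.null(phantom$density))
    return(list(material = phantom$material, density = phantom$density,
                material_names = phantom$material_names))
  m <- hu_to_material(phantom$hu)
  list(material = array(m$material_index, dim(phantom$hu)),
       density = array(m$density, dim(phantom$hu)),
       material_names = m$material_names)
}

# --- CTDI phantom ----------------------------------------------------------

#' Build a CTDI dosimetry phantom
#'
#' PMMA cylinder (density 1.19 g/cm^3) with its axis along z through the
#' isocentre, and the five standard probe axes: centre plus four
#' peripheral probes at 1 cm depth at the 12, 3, 6 and 9 o'clock
#' positions.
#'
#' @param diameter_cm 16 (head) or 32 (body).
#' @param spacing_mm Isotropic voxel spacing, at most 5 mm.
#' @param length_cm Cylinder length (>= 15 cm).
#' @return List with `phantom` (a `voxel_phantom` carrying explicit
#'   material/density arrays) and `probes_mm` (5 x 2 matrix of probe axis
#'   x/y positions, rows named centre/N/E/S/W).
#' @export
make_ctdi_phantom <- function(diameter_cm = 32, spacing_mm = 2.5,
                              length_cm = 15) {
  if (!diameter_cm %in% c(16, 32))
    stop("unsupported CTDI phantom diameter; use 16 or 32 cm")
  if (spacing_mm > 5) stop("spacing must be at most 5 mm")
  if (length_cm < 15) stop("CTDI phantom must be at least 15 cm long")
  r <- diameter_cm * 10 / 2
  half_xy <- r + 2 * spacing_mm
  half_z <- length_cm * 10 / 2
  nx <- ceiling(2 * half_xy / spacing_mm)
  nz <- ceiling(2 * half_z / spacing_mm)
  origin <- c(-nx / 2 * spacing_mm, -nx / 2 * spacing_mm,
              -nz / 2 * spacing_mm)
  cx <- origin[1] + (seq_len(nx) - 0.5) * spacing_mm
  cz <- origin[3] + (seq_len(nz) - 0.5) * spacing_mm
  in_disc <- outer(cx^2, cx^2, "+") <= r^2
  hu <- array(-1000, c(nx, nx, nz))
  mat <- array(1L, c(nx, nx, nz))
  den <- array(0.0012, c(nx, nx, nz))
  disc3 <- array(rep(in_disc, nz), c(nx, nx, nz))
  hu[disc3] <- 120
  mat[disc3] <- 2L
  den[disc3] <- 1.19
  ph <- new_voxel_phantom(hu, rep(spacing_mm, 3), origin,
                          material = mat, density = den,
                          material_names = c("air", "pmma"))
  rp <- r - 10
  probes <- rbind(centre = c(0, 0), N = c(0, rp), E = c(rp, 0),
                  S = c(0, -rp), W = c(-rp, 0))
  colnames(probes) <- c("x_mm", "y_mm")
  list(phantom = ph, probes_mm = probes)
}

# --- Parametric pelvis phantom --------------------------------------------

#' Default parameters of the adult-male pelvis phantom
#'
#' Body and organ dimensions (cm) chosen to match an adult-male trunk:
#' elliptical soft-tissue body, no arms, prostate centred at the
#' isocentre, bladder anterior-superior, rectum posterior, sigmoid colon
#' superior, stomach centred 27 cm superior of the isocentre, femora,
#' pelvic ring and sacrum as cortical shells with spongiosa interiors.
#'
#' @return Named list of parameters accepted by [make_pelvis_phantom()].
#' @export
pelvis_phantom_params <- function() {
  list(
    body_semi_cm = c(17, 11.5),    # lateral, AP semi-axes of the trunk
    body_center_y_cm = 1.5,
    trunk_z_cm = c(-8, 41),
    thigh_semi_cm = c(7.5, 9),
    thigh_center_cm = c(8.5, 0.5), # |x| and y of each thigh axis
    legs_z_cm = c(-25, -8),
    prostate_semi_cm = c(2.1, 1.9, 1.5),
    bladder_center_cm = c(0, 2.5, 6),
    bladder_outer_cm = 4.0,
    bladder_inner_cm = 3.3,
    rectum_center_xy_cm = c(0, -4.3),
    rectum_radius_cm = 1.9,
    rectum_z_cm = c(-4, 8),
    sigmoid_radius_cm = 1.5,
    sigmoid_path_cm = rbind(c(3.5, -2.5, 8.5), c(4.5, 1.5, 12.5),
                            c(-3.5, -0.5, 16)),
    stomach_center_cm = c(5.5, 2, 27),
    stomach_semi_cm = c(4.5, 3.5, 5.5),
    femur_shaft_x_cm = 8.7,
    femur_shaft_y_cm = -0.5,
    femur_shaft_radius_cm = 1.5,
    femur_shaft_z_cm = c(-25, -3),
    femur_head_center_cm = c(6.8, -0.5, 1.0),
    femur_head_radius_cm = 2.2,
    femur_neck_radius_cm = 1.4,
    pelvis_outer_semi_cm = c(13.6, 9.4),
    pelvis_inner_semi_cm = c(12.2, 8.0),
    pelvis_center_y_cm = 1.0,
    pelvis_z_cm = c(-2, 12),
    pubis_outer_semi_cm = c(9.5, 8.0),
    pubis_inner_semi_cm = c(8.3, 6.8),
    pubis_z_cm = c(-6, -2),
    sacrum_z_cm = c(3, 13),
    sacrum_y_cm = c(-9.2, -6.8),
    sacrum_halfwidth_cm = c(1.8, 4.6), # at inferior and superior end
    cortical_shell_cm = 0.35,
    hu = c(air = -1000, soft = 30, organ = 40, urine = 10,
           spongiosa = 260, cortical = 1300)
  )
}

#' Organs guaranteed by the default pelvis phantom
#' @return Character vector of organ mask names.
#' @export
pelvis_organ_names <- function() {
  c("prostate", "bladder_wall", "rectum", "sigmoid_colon", "stomach",
    "femora_spongiosa", "pelvis_spongiosa", "sacrum_spongiosa",
    "cortical_bone", "soft_tissue")
}

#' Generate the parametric adult-male pelvis voxel phantom
#'
#' Analytically posed organs voxelized onto a cell-centred grid; organ
#' masks are painted from a single label volume and are therefore
#' pairwise disjoint by construction.  If a perturbed parameter set makes
#' two organs claim overlapping voxels the function stops with an error
#' rather than silently merging them.  The phantom is deterministic for a
#' fixed seed and parameter set; `jitter_mm > 0` applies reproducible
#' Gaussian position jitter to the soft organs.
#'
#' @param params Parameter list, see [pelvis_phantom_params()].
#' @param spacing_mm Isotropic voxel spacing, at most 5 mm (default 5).
#' @param seed Integer seed for the position jitter.
#' @param jitter_mm Standard deviation of organ-position jitter (mm).
#' @return List with `phantom` (a `voxel_phantom` of Hounsfield units)
#'   and `masks` (an `organ_masks` label set).
#' @export
make_pelvis_phantom <- function(params = pelvis_phantom_params(),
                                spacing_mm = 5, seed = 1, jitter_mm = 0) {
  if (spacing_mm > 5) stop("spacing must be at most 5 mm")
  P <- utils::modifyList(pelvis_phantom_params(), params)
  if (jitter_mm > 0) {
    rng <- .rng_stream(seed)
    jit <- function(v) v + rng(length(v)) * jitter_mm / 10
    P$bladder_center_cm <- jit(P$bladder_center_cm)
    P$rectum_center_xy_cm <- jit(P$rectum_center_xy_cm)
    P$stomach_center_cm <- jit(P$stomach_center_cm)
  }
  sp <- spacing_mm / 10                       # work in cm
  half_x <- P$body_semi_cm[1] + 2.5 * sp
  half_y <- P$body_semi_cm[2] + abs(P$body_center_y_cm) + 2.5 * sp
  z_lo <- P$legs_z_cm[1] - 2 * sp
  z_hi <- P$trunk_z_cm[2] + 2 * sp
  nx <- ceiling(2 * half_x / sp); ny <- ceiling(2 * half_y / sp)
  nz <- ceiling((z_hi - z_lo) / sp)
  origin_cm <- c(-nx / 2 * sp, -ny / 2 * sp, z_lo)
  cx <- origin_cm[1] + (seq_len(nx) - 0.5) * sp
  cy <- origin_cm[2] + (seq_len(ny) - 0.5) * sp
  cz <- origin_cm[3] + (seq_len(nz) - 0.5) * sp
  dm <- c(nx, ny, nz)
  X <- array(rep(cx, times = ny * nz), dm)
  Y <- array(rep(rep(cy, each = nx), times = nz), dm)
  Z <- array(rep(cz, each = nx * ny), dm)

  lab <- array(0L, dm)
  organs <- pelvis_organ_names()
  lid <- stats::setNames(seq_along(organs), organs)

  # body: trunk ellipse plus two thighs
  ell2 <- function(x0, y0, a, b) ((X - x0) / a)^2 + ((Y - y0) / b)^2 <= 1
  trunk <- ell2(0, P$body_center_y_cm, P$body_semi_cm[1], P$body_semi_cm[2]) &
    Z >= P$trunk_z_cm[1] & Z <= P$trunk_z_cm[2]
  thighs <- (ell2(P$thigh_center_cm[1], P$thigh_center_cm[2],
                  P$thigh_semi_cm[1], P$thigh_semi_cm[2]) |
             ell2(-P$thigh_center_cm[1], P$thigh_center_cm[2],
                  P$thigh_semi_cm[1], P$thigh_semi_cm[2])) &
    Z >= P$legs_z_cm[1] & Z < P$legs_z_cm[2]
  lab[trunk | thighs] <- lid[["soft_tissue"]]

  shell <- P$cortical_shell_cm
  paint_bone <- function(outer, inner, spong_label) {
    if (any(lab[outer] != lid[["soft_tissue"]] & lab[outer] != 0L &
            lab[outer] != lid[["cortical_bone"]] &
            lab[outer] != lid[[spong_label]]))
      stop("bone '", spong_label, "' collides with another organ")
    lab[outer & !inner] <<- lid[["cortical_bone"]]
    lab[inner] <<- lid[[spong_label]]
  }

  # femora: head sphere + neck capsule + shaft cylinder, each with a
  # cortical shell of `shell` cm
  for (s in c(-1, 1)) {
    hc <- P$femur_head_center_cm * c(s, 1, 1)
    head_o <- (X - hc[1])^2 + (Y - hc[2])^2 + (Z - hc[3])^2 <=
      P$femur_head_radius_cm^2
    head_i <- (X - hc[1])^2 + (Y - hc[2])^2 + (Z - hc[3])^2 <=
      (P$femur_head_radius_cm - shell)^2
    a <- hc
    b <- c(s * P$femur_shaft_x_cm, P$femur_shaft_y_cm, P$femur_shaft_z_cm[2])
    ab <- b - a
    tproj <- pmin(pmax(((X - a[1]) * ab[1] + (Y - a[2]) * ab[2] +
                          (Z - a[3]) * ab[3]) / sum(ab^2), 0), 1)
    d2 <- (X - (a[1] + tproj * ab[1]))^2 + (Y - (a[2] + tproj * ab[2]))^2 +
      (Z - (a[3] + tproj * ab[3]))^2
    neck_o <- d2 <= P$femur_neck_radius_cm^2
    neck_i <- d2 <= (P$femur_neck_radius_cm - shell)^2
    shaft_r2 <- (X - s * P$femur_shaft_x_cm)^2 + (Y - P$femur_shaft_y_cm)^2
    in_shaft_z <- Z >= P$femur_shaft_z_cm[1] & Z <= P$femur_shaft_z_cm[2]
    shaft_o <- shaft_r2 <= P$femur_shaft_radius_cm^2 & in_shaft_z
    shaft_i <- shaft_r2 <= (P$femur_shaft_radius_cm - shell)^2 & in_shaft_z
    paint_bone(head_o | neck_o | shaft_o, head_i | neck_i | shaft_i,
               "femora_spongiosa")
  }

  # pelvic ring (iliac/main ring plus inferior pubis/ischium ring), with
  # a posterior notch left open for the sacrum
  notch <- Y - P$pelvis_center_y_cm < -3 & abs(X) < 4.8
  ring_zone <- Z >= P$pelvis_z_cm[1] & Z <= P$pelvis_z_cm[2] & !notch
  ring_o <- ring_zone &
    ell2(0, P$pelvis_center_y_cm, P$pelvis_outer_semi_cm[1],
         P$pelvis_outer_semi_cm[2]) &
    !ell2(0, P$pelvis_center_y_cm, P$pelvis_inner_semi_cm[1],
          P$pelvis_inner_semi_cm[2])
  ring_i <- ring_zone &
    ell2(0, P$pelvis_center_y_cm, P$pelvis_outer_semi_cm[1] - shell,
         P$pelvis_outer_semi_cm[2] - shell) &
    !ell2(0, P$pelvis_center_y_cm, P$pelvis_inner_semi_cm[1] + shell,
          P$pelvis_inner_semi_cm[2] + shell)
  # inferior ring kept to the anterior arch (pubis); the posterior rami
  # are omitted so the rectum and femoral necks stay clear of bone
  pub_zone <- Z >= P$pubis_z_cm[1] & Z < P$pubis_z_cm[2] &
    Y - P$pelvis_center_y_cm > 0
  pub_o <- pub_zone &
    ell2(0, P$pelvis_center_y_cm, P$pubis_outer_semi_cm[1],
         P$pubis_outer_semi_cm[2]) &
    !ell2(0, P$pelvis_center_y_cm, P$pubis_inner_semi_cm[1],
          P$pubis_inner_semi_cm[2])
  pub_i <- pub_zone &
    ell2(0, P$pelvis_center_y_cm, P$pubis_outer_semi_cm[1] - shell,
         P$pubis_outer_semi_cm[2] - shell) &
    !ell2(0, P$pelvis_center_y_cm, P$pubis_inner_semi_cm[1] + shell,
          P$pubis_inner_semi_cm[2] + shell)
  paint_bone(ring_o | pub_o, ring_i | pub_i, "pelvis_spongiosa")

  # sacrum: posterior wedge widening superiorly
  zfrac <- (Z - P$sacrum_z_cm[1]) / diff(P$sacrum_z_cm)
  w <- P$sacrum_halfwidth_cm[1] +
    (P$sacrum_halfwidth_cm[2] - P$sacrum_halfwidth_cm[1]) * zfrac
  sac_zone <- Z >= P$sacrum_z_cm[1] & Z <= P$sacrum_z_cm[2]
  sac_o <- sac_zone & Y >= P$sacrum_y_cm[1] & Y <= P$sacrum_y_cm[2] &
    abs(X) <= w
  sac_i <- sac_zone & Z >= P$sacrum_z_cm[1] + shell &
    Z <= P$sacrum_z_cm[2] - shell &
    Y >= P$sacrum_y_cm[1] + shell & Y <= P$sacrum_y_cm[2] - shell &
    abs(X) <= w - shell
  paint_bone(sac_o, sac_i, "sacrum_spongiosa")

  paint_organ <- function(mask, organ) {
    bad <- lab[mask] != lid[["soft_tissue"]]
    if (any(bad))
      stop("organ '", organ, "' collides with ",
           paste(unique(organs[lab[mask][bad]]), collapse = ", "),
           " (or falls outside the body); adjust the parameters")
    lab[mask] <<- lid[[organ]]
  }

  pr <- P$prostate_semi_cm
  paint_organ((X / pr[1])^2 + (Y / pr[2])^2 + (Z / pr[3])^2 <= 1, "prostate")
  bc <- P$bladder_center_cm
  bl_r2 <- (X - bc[1])^2 + (Y - bc[2])^2 + (Z - bc[3])^2
  paint_organ(bl_r2 <= P$bladder_outer_cm^2 & bl_r2 > P$bladder_inner_cm^2,
              "bladder_wall")
  bladder_contents <- bl_r2 <= P$bladder_inner_cm^2
  rc <- P$rectum_center_xy_cm
  paint_organ((X - rc[1])^2 + (Y - rc[2])^2 <= P$rectum_radius_cm^2 &
                Z >= P$rectum_z_cm[1] & Z <= P$rectum_z_cm[2], "rectum")
  # sigmoid: tube around a quadratic Bezier path, via dense path sampling
  tt <- seq(0, 1, length.out = 120)
  B <- outer((1 - tt)^2, P$sigmoid_path_cm[1, ]) +
    outer(2 * tt * (1 - tt), P$sigmoid_path_cm[2, ]) +
    outer(tt^2, P$sigmoid_path_cm[3, ])
  mind2 <- array(Inf, dm)
  for (i in seq_along(tt)) {
    d2 <- (X - B[i, 1])^2 + (Y - B[i, 2])^2 + (Z - B[i, 3])^2
    mind2 <- pmin(mind2, d2)
  }
  paint_organ(mind2 <= P$sigmoid_radius_cm^2, "sigmoid_colon")
  sc <- P$stomach_center_cm; ss <- P$stomach_semi_cm
  paint_organ(((X - sc[1]) / ss[1])^2 + ((Y - sc[2]) / ss[2])^2 +
                ((Z - sc[3]) / ss[3])^2 <= 1, "stomach")

  hu <- array(P$hu[["air"]], dm)
  hu[lab == lid[["soft_tissue"]]] <- P$hu[["soft"]]
  for (o in c("prostate", "bladder_wall", "rectum", "sigmoid_colon",
              "stomach"))
    hu[lab == lid[[o]]] <- P$hu[["organ"]]
  hu[bladder_contents] <- P$hu[["urine"]]
  for (o in c("femora_spongiosa", "pelvis_spongiosa", "sacrum_spongiosa"))
    hu[lab == lid[[o]]] <- P$hu[["spongiosa"]]
  hu[lab == lid[["cortical_bone"]]] <- P$hu[["cortical"]]

  empty <- organs[!organs %in% organs[sort(unique(lab[lab > 0]))]]
  if (length(empty))
    stop("empty organ mask(s): ", paste(empty, collapse = ", "))

  phantom <- new_voxel_phantom(hu, rep(spacing_mm, 3), origin_cm * 10)
  masks <- structure(list(labels = lab, organs = lid,
                          spacing_mm = phantom$spacing_mm,
                          origin_mm = phantom$origin_mm),
                     class = "organ_masks")
  list(phantom = phantom, masks = masks)
}

# deterministic standard-normal stream independent of the global RNG
.rng_stream <- function(seed) {
  env <- new.env()
  env$state <- as.integer(seed)
  function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else if (exists(".Random.seed", globalenv()))
              rm(".Random.seed", envir = globalenv()))
    set.seed(env$state)
    env$state <- env$state + 1L
    stats::rnorm(n)
  }
}

#' Linear voxel indices of an organ mask
#'
#' @param masks An `organ_masks` set.
#' @param organ Organ name.
#' @return Integer vector of linear indices into the phantom arrays.
#' @export
organ_indices <- function(masks, organ) {
  stopifnot(inherits(masks, "organ_masks"))
  if (!organ %in% names(masks$organs)) stop("unknown organ '", organ, "'")
  which(masks$labels == masks$organs[[organ]])
}

# --- Volume I/O ------------------------------------------------------------

#' Write a voxel phantom to a NIfTI volume
#'
#' Losslessly stores the Hounsfield grid, voxel spacing and origin
#' (via the NIfTI sform).
#'
#' @param volume A `voxel_phantom`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_phantom"))
  img <- RNifti::asNifti(volume$hu, datatype = "float")
  xf <- diag(c(volume$spacing_mm, 1))
  xf[1:3, 4] <- volume$origin_mm + volume$spacing_mm / 2
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a voxel phantom from a NIfTI volume
#'
#' @param path Path written by [write_volume()] (or any scalar 3-D NIfTI
#'   volume holding Hounsfield units).
#' @return A `voxel_phantom`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  spacing <- abs(diag(xf)[1:3])
  origin <- xf[1:3, 4] - spacing / 2
  new_voxel_phantom(array(as.numeric(img), dim(img)[1:3]), spacing, origin)
}

# --- Synthetic survey records ----------------------------------------------

#' Generate synthetic CTDI_w survey records
#'
#' Reproducible stand-in for a hospital questionnaire: each hospital
#' reports `protocols_per_hospital` CTDI_w values drawn from a log-normal
#' distribution, and an imaging-frequency answer drawn with the surveyed
#' proportions (74% every fraction, 21% first 1-3 fractions, 5% first
#' 4-7).
#'
#' @param n_countries Number of countries (coded A, B, ...).
#' @param hospitals_per_country Hospitals per country.
#' @param site Treatment site label for all records.
#' @param meanlog,sdlog Log-normal parameters of CTDI_w in mGy
#'   (`sdlog = 0` gives the degenerate distribution at `exp(meanlog)`).
#' @param protocols_per_hospital Records per hospital.
#' @param seed Integer seed.
#' @return Data frame with columns `country`, `hospital`, `site`,
#'   `ctdiw_mGy`, `imaging_frequency`.
#' @export
generate_survey_records <- function(n_countries = 10,
                                    hospitals_per_country = 4,
                                    site = "pelvis",
                                    meanlog = log(12), sdlog = 0.4,
                                    protocols_per_hospital = 2,
                                    seed = 1) {
  stopifnot(n_countries >= 1, hospitals_per_country >= 1,
            protocols_per_hospital >= 1, sdlog >= 0)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  countries <- make.unique(c(LETTERS, paste0("Z", 1:100)))[1:n_countries]
  rows <- expand.grid(proto = seq_len(protocols_per_hospital),
                      hospital = seq_len(hospitals_per_country),
                      country = countries, stringsAsFactors = FALSE)
  n <- nrow(rows)
  data.frame(
    country = rows$country,
    hospital = paste0(rows$country, rows$hospital),
    site = site,
    ctdiw_mGy = stats::rlnorm(n, meanlog, sdlog),
    imaging_frequency = sample(c("every_fraction", "first_1_3", "first_4_7"),
                               n, replace = TRUE, prob = c(0.74, 0.21, 0.05)),
    stringsAsFactors = FALSE
  )
}
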