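---
title: "Organ dosimetry for kV-CBCT positioning imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Organ dosimetry for kV-CBCT positioning imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cbctdose` estimates mean absorbed organ doses per imaged fraction for
kilovoltage cone-beam CT (kV-CBCT) patient-positioning imaging in the
pelvic region, together with the survey statistics used for
diagnostic-reference-level (DRL) benchmarking of CTDI~w~.  This vignette
is the package's account of its models, assumptions, parameters and
limitations.

## The dose chain

A clinical CBCT protocol is described by its tube potential $U$ (kV),
tube current-time product $Q$ (mAs), weighted CT dose index CTDI~w~
(mGy), projection count and gantry arc, imaged-region length, field of
view (FOV) and fan mode (full or half).  The package reproduces the
absolute organ-dose chain used with Monte Carlo CBCT dose engines:

1. **Tube spectrum.** A semi-empirical tungsten-anode model generates
   the fluence spectrum for the protocol's kV.
2. **Beam model.** The protocol's aperture at the isocentre plane is
   derived from FOV, imaged length and the source-to-isocentre distance
   (SID); a bowtie filter modulates fluence and hardness across the fan.
3. **Monte Carlo transport.** Photons are transported through a voxel
   phantom by Woodcock tracking; per-voxel absorbed dose is scored in
   keV/g per simulated source photon.
4. **Absolute normalization.** The conversion setup — a 32 cm PMMA CTDI
   phantom, full-fan beam of 16° total fan angle, 10 cm collimation,
   full rotation — is simulated once per spectrum/bowtie pairing to
   obtain the factor $f = K_a / \mathrm{CTDI_w}$ between air kerma
   free-in-air at the isocentre and CTDI~w~.  The protocol's printed
   CTDI~w~ then fixes $K_a = f \cdot \mathrm{CTDI_w}$, and all voxel
   doses are scaled by the single constant
   $f \cdot \mathrm{CTDI_w} / K_{a,\mathrm{sim}}$, where
   $K_{a,\mathrm{sim}}$ is the simulated per-photon kerma under the
   protocol's own source model.  Because kerma appears in both numerator
   and denominator, the chain effectively compares the organ dose per
   photon with the conversion-setup CTDI~w~ per photon; estimator biases
   largely cancel.
5. **Organ statistics.** Organ doses are arithmetic means over mask
   voxels; red-bone-marrow (RBM) doses are derived from spongiosa doses
   by the three-parameter mass-energy-absorption-coefficient (MEAC)
   method; uncertainties come from batch bootstrap.

## Spectrum model

`generate_spectrum()` implements a Kramers bremsstrahlung continuum,
$\Phi(E) \propto (U - E)/E$, attenuated by the anode's own tungsten at
an energy-dependent production depth given by the Thomson–Whiddington
penetration law (constant $7.6\times10^5$ keV² cm²/g) divided by
$\sin(\theta_A)$ for anode angle $\theta_A$.  Above the tungsten K edge
(69.5 keV) the four K characteristic lines are added with a total
fluence fraction calibrated to ~9% at 120 kV.  Filtration (inherent and
added) is Beer–Lambert per bin.  Defaults: anode angle 14°, inherent
filtration 2.5 mm Al — typical values for linac-mounted kV tubes; the
survey did not report per-machine values, so both are declared
assumptions exposed as arguments.  The grid is 1 keV bins from 5 keV to
the tube potential.  At 120 kV/2.5 mm Al the model yields a mean energy
of ~57 keV and a first half-value layer of ~5.3 mm Al, in the range
reported for clinical CBCT tubes.

## Interaction data and transport physics

Total mass attenuation and mass energy-absorption coefficients for
water, air, aluminum, PMMA, soft tissue, cortical bone and a spongiosa
mixture (35% cortical bone, 65% soft tissue by mass) are embedded at
the standard sparse energy nodes and log-log interpolated to a 1 keV
working grid from 5 to 150 keV.  The interaction partition anchors the
three channels as follows: incoherent scattering is Klein–Nishina times
the electron density (free-electron approximation); photoelectric
absorption is derived from the energy-absorption tables,
$\tau \approx \mu_{en} - \mu_{inc} f_T(E)$, where $f_T$ is the
Klein–Nishina mean energy-transfer fraction; coherent scattering is the
non-negative remainder.  The three channels therefore sum exactly to
the tabulated total — attenuation is exact by construction, while the
split between channels is approximate at the few-percent level.

Transport uses Woodcock (delta) tracking with a per-energy majorant
over the materials present in the grid.  Interactions: photoelectric —
full local deposit; Compton — Klein–Nishina free-electron sampling by
rejection on the scattering angle, with the Compton electron deposited
locally; Rayleigh — Thomson angular law without atomic form factors
(toggleable to forward pass-through; the real coherent distribution is
more forward-peaked, a documented approximation).  Photons below 5 keV
deposit locally; escaping photons are dropped.  Scoring is collision
kerma: at or below 125 kV the CSDA range of secondary electrons is well
below the 5 mm voxel size, so local deposition at the interaction site
is the standard approximation.  The engine was cross-checked against an
independently coded analog Monte Carlo on a broad-beam water slab
(scatter-to-primary ratios agreeing along the depth-dose curve) and
against closed-form narrow-beam attenuation.

The random-number generator is a PCG32 stream seeded independently per
batch from the user seed, so results are bit-reproducible for a fixed
seed and batch count and batches are statistically independent.

## Source and bowtie model

Each photon samples a projection angle uniformly from the protocol's
schedule (angles uniformly spaced along the signed start-to-stop arc),
a position uniformly over the field rectangle at the isocentre plane,
and an energy from the spectrum attenuated by the bowtie's
aluminum-equivalent thickness at the photon's fan angle; the photon
weight is the bowtie's transmitted fluence fraction.  Half-fan
apertures cover $[-2.5\ \mathrm{cm}, \mathrm{FOV}/2]$ at the isocentre
(offset-detector geometry with a fixed past-centre overlap), full-fan
apertures are symmetric.  Default distances are SID 100 cm and SDD
150 cm (Varian) / 153.6 cm (Elekta).

The exact vendor bowtie shapes were not available; the three shipped
profiles are parametric stand-ins chosen for the published character of
each family: the Varian half-fan filter has a 2 mm Al plateau offset
+2 cm from the axis rising monotonically to ~28–30 mm Al at the wide
field edge with a steep cut on the narrow side; the Elekta filter
cassette is much milder ($0.1 + 0.14(\psi - 2°)^2$ mm Al); the
full-fan bowtie is symmetric.  With these profiles the simulated
$K_a/\mathrm{CTDI_w}$ conversion factor is ~3.8 (120 kV, Elekta
filter) and ~4.6 (125 kV, Varian half-fan), consistent with published
linac kV-system outputs.  Profiles are tabulated per degree and can be
replaced by the user.

## The synthetic pelvis phantom

The licensed adult reference voxel phantom cannot be redistributed, so
`make_pelvis_phantom()` builds a parametric stand-in: an elliptical
adult-male trunk (34 × 23 cm at the pelvis, arms removed, mid-thigh to
mid-thorax so that 41 cm imaged regions fit), splitting into two thighs
below the crotch.  Organs are analytically posed: prostate (25 cm³
ellipsoid) centred at the isocentre; bladder wall as a spherical shell
anterior-superior; rectum posterior; sigmoid colon as a curved tube
superior; stomach centred 27 cm superior — far enough that only the
longest imaged regions reach it; femora (head, neck, shaft), pelvic
ring and sacrum as cortical shells (3.5 mm) with spongiosa interiors.
Bone masses total ~0.9 L, matching the plate-like character of real
pelvic bones — an earlier, chunkier ring measurably suppressed the
interior scatter bath and was corrected on anatomical grounds.  Organ
positions were chosen so the dose gradients that drive the published
protocol differences are reproduced: the stomach lies beyond the
superior field edge of all but the longest protocols, the femora sit at
the inferior field edge, and the sacrum (3–13 cm superior) is clipped
by short prostate fields but fully covered by long ones.

Hounsfield units are assigned per material and mapped back to density
and transport material by a monotone piecewise rule anchored at water
(HU 0 → 1.00 g/cm³) with a linear bone ramp reaching cortical density
at HU 1300.  Masks are painted into a single label volume, so they are
pairwise disjoint by construction, and any parameter perturbation that
makes organs collide raises an error instead of silently overlapping.
Default spacing is 5 mm isotropic (2.5 mm supported), keeping organ
masks at tens-to-thousands of voxels while transport runs in seconds;
the voxelized body mass changes by <2% when the spacing is halved.

What the phantom does *not* emulate: real anatomical texture
(intestinal gas, marrow distribution within trabeculae, cortical
thickness variation), patient-to-patient size variation, and the exact
reference-phantom organ topology.  Agreement of the pipeline's absolute
doses with published reference-phantom values is therefore expected
only within a broad (~25%) band, and passing tests demonstrate the
correctness of the chain, not anatomical fidelity.

## CTDI, normalization and uncertainties

`compute_ctdiw()` extracts the dose profile along each probe axis
(averaged over a 5 mm-radius pencil-chamber-sized column to control
Monte Carlo noise), integrates it over ±50 mm by the trapezoid rule
with linear interpolation at the half-voxel edges, divides by the
collimation, and combines centre and periphery with the standard
1/3 + 2/3 weighting — an identity asserted exactly in the tests.

`bootstrap_uncertainty()` resamples the per-batch organ contributions
(1000 resamples by default) and reports the standard deviation of the
resampled means; batch-level resampling was chosen over voxel-level
because voxel doses within an organ are strongly correlated within a
batch.  `combine_uncertainties()` adds independent relative
uncertainties in quadrature.

## Red bone marrow

RBM is not segmented in reference phantoms; its dose is estimated from
the spongiosa dose as
$D_{RBM} = D_{spong}\,\langle r \rangle_w \langle \mathrm{DEF}
\rangle_w$ with $r$ the RBM-to-spongiosa mass-energy-absorption-
coefficient ratio and DEF the dose enhancement factor from
photoelectrons released in trabecular bone.  The weighting uses the
initial tube spectrum as the estimate of the fluence at the marrow
site, with per-bin weights $\Phi E (\mu_{en}/\rho)_{spong}$ — i.e. by
the quantity being converted (the spongiosa collision kerma), a
declared design choice where the convention was ambiguous.  The shipped
factor table is a synthetic reconstruction (see the file header): MEAC
ratios recomputed from the embedded marrow/spongiosa energy-absorption
data with small site offsets, DEF a smooth curve peaking ~1.25–1.3 near
50 keV.  Published skeletal-dosimetry tables can be substituted via
`rbm_factors(path)`.

## Numerical choices and degenerate inputs

* Energy grids: spectra on 1 keV bins, cross sections on a 1 keV grid
  5–150 keV with linear interpolation inside the engine.
* Tie-breaks and conventions: gantry 0° places the source anterior;
  arcs follow the signed start-to-stop difference ("full rotation"
  entries are encoded −180..180); the regional DRL uses the lower
  median for even counts (reproducing the published value where the
  midpoint would not); national DRLs use the type-7 quantile.
* Degenerate inputs: zero photons give a zero grid; zero-thickness
  filtration and zero-thickness bowties are identities; single-batch
  uncertainty, empty organ masks, unknown materials and points outside
  the beam aperture raise errors.
* Desk-scale defaults: 2×10⁶ photons in 50 batches per protocol
  (production runs of this kind use ≥10¹⁰); with the C++ engine this is
  seconds per protocol, and the statistical noise is carried explicitly
  by the batch bootstrap (~1–4% for in-beam organs).

## Known limitations

* The printed CTDI~w~ values that anchor the absolute scale are
  vendor-provided survey answers of mixed provenance; under a single
  consistent physics chain the organ-dose-to-CTDI~w~ ratios they imply
  differ by more than a factor of two between machines of the same
  vendor and tube potential.  Comparisons against published per-protocol
  doses therefore inherit this inconsistency, and one protocol cannot
  always be matched without unmatching another.
* No coupled electron transport; no atomic form factors or Doppler
  broadening; bowtie shapes are parametric approximations; the phantom
  is a geometric stand-in.
* Female anatomy, arms-in setups, thorax and head-and-neck protocols,
  image formation and image-quality QA are out of scope.
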