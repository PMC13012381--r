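Package: cbctdose
Title: Organ Dosimetry for Kilovoltage Cone-Beam CT Positioning Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale dosimetry pipeline for patient-positioning kV
    cone-beam CT (CBCT) in image-guided radiotherapy. Generates
    kilovoltage X-ray tube spectra from a semi-empirical tungsten-anode
    model, models CBCT acquisition geometry and bowtie filters for a
    registry of clinical pelvis and prostate protocols, transports
    photons through voxel phantoms by Woodcock (delta) tracking under
    the collision-kerma approximation, and converts the simulated dose
    grids to absolute mean organ doses per imaged fraction through the
    weighted CT dose index (CTDI_w) to air-kerma chain. Includes a
    parametric adult-male pelvis voxel phantom with organ masks, red
    bone marrow dosimetry via spectrum-weighted mass-energy-absorption
    coefficient ratios and dose enhancement factors, bootstrap
    uncertainty estimation, and diagnostic-reference-level (DRL)
    statistics for CTDI_w surveys.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
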