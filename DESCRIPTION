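Package: ctdosim
Title: Monte Carlo Organ Dosimetry and Lung-Cancer Risk for Helical 4DCT
    and Axial CT Thoracic Scans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Desk-scale pipeline for estimating organ doses delivered by
    low-pitch helical 4DCT versus conventional axial 3DCT thoracic scans and
    the associated BEIR VII excess relative risk of lung cancer. Builds
    voxelized thorax phantoms (from Hounsfield-unit volumes or a parametric
    synthetic generator), discretizes axial and helical CT source
    trajectories into coplanar gantry fields, transports kilovoltage photons
    through the phantom with a Woodcock-tracked kerma-approximation Monte
    Carlo kernel, converts per-history dose to absolute dose via a CTDI
    phantom conversion factor, and fits the linear organ-dose versus
    effective-diameter relationship feeding the sex-specific excess relative
    risk model.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
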