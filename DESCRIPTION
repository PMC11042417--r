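Package: spectre
Title: Volumetric Reconstruction of Brain Electric Fields from EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models brain electric-field waves in inhomogeneous, anisotropic
    head tissue and reconstructs the volumetric electric potential from scalp
    EEG recordings. Provides a tissue-labelled head model with voxelwise
    bioelectric property fields, dispersion-relation analytics for damped
    tissue waves and thin boundary-layer modes, a pseudo-spectral time-domain
    wave simulator with wave-loop detection, a synthetic-EEG forward
    generator, an iterative frequency-domain inverse solver that fits a
    complex volumetric potential per frequency band to electrode data, and an
    entropy-based spatiotemporal mode decomposition with map-comparison
    statistics. All solvers operate on periodic voxel grids using FFT-based
    spatial derivatives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
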