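Package: cordDTI
Title: Column-Specific Spinal Cord Diffusion Tensor Imaging at C2
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processing pipeline for single-slice axial diffusion tensor
    imaging (DTI) of the cervical spinal cord. Provides a digital cord
    phantom with known ground truth (elliptical cord, butterfly gray
    matter, CSF ring, per-volume anterior-posterior motion, Rician noise),
    readers and writers for NIfTI images with FSL-style gradient tables,
    midsagittal-profile motion correction, per-pixel log-linear tensor
    fitting with FA/MD/RD/AD scalar maps, metric-map interpolation, a
    semi-automated ellipse and angular-profile method that locates the
    posterior horns and places bilateral circular regions of interest on
    the pyramidal tracts, dorsal columns and anterior horns, and a cohort
    statistics layer (variance-gated two-sample tests, Bonferroni
    correction, covariate-adjusted effect sizes, correlation and quadratic
    regression against clinical scores).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    emmeans,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
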