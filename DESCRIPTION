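Package: vertebrofe
Title: Specimen-Specific Voxel Finite-Element Models of Vertebral Cement
    Augmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and solves specimen-specific voxel-hexahedral
    finite-element models of human lumbar vertebrae from micro-CT-style
    image stacks, before and after cement augmentation (vertebroplasty).
    Provides two bone material-mapping routes (direct grayscale and bone
    volume fraction), connectivity-based threshold selection,
    three-landmark rigid registration of longitudinal scans, cement and
    needle-track mask superposition with an elastic-perfectly-plastic
    cement-bone interface layer, a small-strain linear and elastoplastic
    solver for voxel meshes, stiffness extraction from load-displacement
    curves, grayscale-to-modulus conversion-factor calibration with
    build/validation splits, and Lin's concordance correlation
    statistics. Includes a synthetic vertebra phantom generator with
    known ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    jsonlite,
    tiff,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
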