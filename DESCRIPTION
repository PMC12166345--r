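Package: smlmz
Title: Model-Free Axial Localisation for 3D Single-Molecule Localisation Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns a microscope's spatially varying axial point-spread-function
    signature from calibration bead Z-stacks with a lightweight two-branch
    convolutional neural network, assigns axial (Z) positions to 2D
    single-molecule localisations, corrects axial drift with a windowed
    smoothed spline, and scores 3D reconstructions of nuclear-pore-like
    double-ring structures by kernel density estimation. Includes a seeded
    synthetic point-spread-function and acquisition simulator so that every
    stage of the pipeline can be exercised and validated without microscope
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    Matrix,
    tiff,
    yaml,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
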