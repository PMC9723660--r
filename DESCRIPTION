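Package: micropHmap
Title: Microscale pH Mapping from Ratiometric Whole-Cell Biosensor Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Analysis pipeline for micrometre-scale pH mapping with
    immobilized ratiometric (dual-excitation pHluorin2) whole-cell
    biosensors. Converts two-channel fluorescence image stacks into
    per-cell excitation ratios, calibrates ratios to pH with a linear
    standard curve, interpolates per-cell pH onto regular micrometre
    grids by inverse distance weighting with leave-one-out
    cross-validated resolution selection, and summarizes temporal
    dynamics (acidification trajectories, microscale gradients and their
    stability, acidification onset, zone-of-influence and diffusion-time
    estimates). Includes a synthetic-scene generator that renders
    ground-truth pH fields into realistic noisy image stacks so the full
    pipeline is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, CellBasedAssays, Spatial, Visualization
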