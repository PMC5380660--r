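Package: mediaperm
Title: Medial Microstructure Permeability and Arterial Wall Resistance
    Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to estimate the hydraulic permeability of the arterial
    tunica media from three-dimensional microstructural image volumes and to
    decompose total wall hydraulic resistance into medial and intimal
    components.  Includes a seeded generator of synthetic medial
    microstructures (fusiform smooth muscle cells packed helically in
    extracellular matrix) and an emulator of confocal acquisition, image
    processing steps (depth-attenuation correction, rotation to cylindrical
    axes, thresholding, ECM volume fraction, per-slice watershed cell
    segmentation with aspect-ratio statistics, medial thickness), a
    penalised Brinkman flow solver on the voxel grid, least-squares
    homogenisation of directional flow solutions into a symmetric
    permeability tensor with principal components, and series resistance
    decomposition with group statistics and ECM-permeability sensitivity
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    ggplot2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
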