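Package: thynseg
Title: Improved Normalized-Cut Segmentation of Thyroid Ultrasound Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation pipeline for B-mode thyroid ultrasound images built
    around a recursive normalized-cut (Ncut) spectral partitioner. Before graph
    partitioning the image is enhanced by homomorphic contrast compression,
    edge-enhancing anisotropic diffusion in gradient/tangent local coordinates,
    and a Gruenwald-Letnikov fractional-differential gradient operator. Includes
    a synthetic speckle-phantom generator with ground-truth masks, Dice-based
    evaluation utilities, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    EBImage,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: ImageProcessing, Segmentation, Software
RoxygenNote: 7.3.3
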