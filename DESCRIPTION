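Package: historeg
Title: Atlas Registration and Cell Quantification for Coronal Mouse Brain Histology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A semiautomated neurohistology pipeline for registering 2D coronal
    mouse-brain section images to oblique slices of a 3D reference atlas. A
    composite transformation (Mattes mutual-information affine stage followed by
    a B-spline deformable stage driven by neighborhood correlation) warps atlas
    region annotations onto experimental tissue, optionally ignoring damaged
    areas via masks. Cell-body-like signals are found by tiled blob detection
    with non-maximum suppression across overlapping tiles, and signals are
    quantified per anatomical region with ontology roll-up. A synthetic phantom
    generator (phantom volumes, deformed sections with known ground-truth
    transforms, scattered synthetic cells) makes every stage testable without
    external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    png,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
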