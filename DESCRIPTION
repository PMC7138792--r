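Package: xylometry
Title: 3D Morphometry of Plant Cell Walls from Nanotomography Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative 3D morphometry of plant tissue tomograms at the
    cell-wall scale. Provides segmentation of cell wall versus lumen by
    trainable pixel classification and morphological refinement, 3D local
    thickness mapping (largest inscribed sphere), per-slice Euclidean
    distance transform measurements of lumen diameter and medial-axis wall
    thickness, the xylem vessel implosion-resistance parameter (t/b)^2
    profiled along the cellular height, Fourier shell correlation with the
    half-bit resolution criterion, and conversion of refractive-index
    decrement volumes to electron density. A synthetic phantom generator
    with exactly known wall and lumen geometry supports validation of every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    ranger,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
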