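Package: cochleaCT
Title: Quantitative X-Ray Tomography and Morphometry of the Mouse Cochlea
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for quantitative parallel-beam
    X-ray micro-tomography of the mouse cochlea. Generates voxelized spiral
    cochlea phantoms with exactly known centerline length and per-scala
    cross-sectional area profiles, simulates projection acquisition
    (flat/dark fields, Poisson noise, ring artifacts, phenomenological
    edge enhancement), applies flat/dark-field correction and 2x2 binning,
    reconstructs volumes by row-wise filtered backprojection, segments by
    global threshold with largest-component couch removal and sparse-slice
    label propagation, and measures pillar-head centerline length and
    perpendicular cross-sectional area profiles of the scalae.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    pracma,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
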