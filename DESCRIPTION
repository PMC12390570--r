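Package: radiclen
Title: Instance Segmentation and Arc-Length Regression for Germinating
    Seed Radicles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for measuring the curved radicles of germinating elm
    seeds from top-down petri-dish images. Implements a dual-path
    instance-segmentation and length-regression network (feature-pyramid
    backbone with squeeze-and-excitation recalibration, anchor-free
    detection heads with centerness, per-instance attention blending, and
    a convolutional length regressor), pixel-to-millimetre grid
    calibration, COCO-style evaluation with grouped error reports, a
    skeleton-counting baseline, and a parametric germination-scene
    simulator with analytic three-dimensional ground truth for training
    and benchmarking without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
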