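Package: avsmotion
Title: Unsupervised Artificial Visual System for Motion Direction
    Detection
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Two-layer biomimetic model of retinal motion processing.  A
    layer of direction-selective dendritic neurons (local motion
    detection neurons) detects one-pixel motion in eight directions from
    a pair of consecutive image frames, and a Gaussian mixture model
    fitted by expectation-maximization self-organizes those neurons into
    eight global direction detectors without any labels.  Includes
    synthetic stimulus generators (uniformly coloured moving objects
    corrupted by static pixel noise), a from-scratch EM implementation
    with log-space density evaluation, deterministic label calibration, a
    population argmax read-out of global motion direction, and evaluation
    utilities for accuracy grids over object size and noise level.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
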