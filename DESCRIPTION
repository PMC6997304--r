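Package: pelletscan
Title: Micro-CT Image Analysis and Classification for Multi-Particulate
    Capsule Formulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative structural analysis of X-ray microtomography
    (micro-CT) scans of pellet-filled capsules. Provides marker-controlled
    3D watershed segmentation of touching pellets, a global capsule volume
    partition (shell, inter-pellet void, intra-pellet porosity), a
    registry-driven battery of 206 morphological features per pellet
    (including translation- and rotation-invariant 2D cross-sections
    derived from image moments), a sensitivity screen for feature
    robustness against image quality, ReliefF feature ranking, and one-
    and two-class support vector machine models for the detection of
    broken pellets. A deterministic synthetic capsule phantom supplies
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    lhs,
    jsonlite,
    tiff,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
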