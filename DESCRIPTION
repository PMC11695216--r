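Package: ablashape
Title: Simulation and Repeatability Analysis of Configurable Thermal Ablation Shapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico pipeline for studying the repeatability of
    configurable microwave ablation shapes produced by modulating power,
    time and probe retraction distance. Provides ablation profile
    definition and kinematic discretization, an axisymmetric explicit
    finite-difference heat-conduction simulator with a moving volumetric
    source and irreversible coagulation-threshold recording, a synthetic
    generator of thermochromic tissue-phantom cross-section images,
    HSV color-based two-class segmentation, contour morphometry (widths
    at fixed axial steps, head/tail lengths, revolved volume and
    sphericity), a robust pairwise-difference repeatability statistic,
    Mann-Whitney noninferiority testing, and a simulation-based
    sample-size procedure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
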