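Package: StainKinetics
Title: Contrast-Agent Staining Kinetics for X-Ray Computed Tomography of
    Ligaments and Tendons
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of contrast-agent diffusion kinetics in X-ray computed
    tomography of dense connective tissue. Extracts width-averaged line
    profiles from tomographic slices, detects sample edges and stain fronts
    with gradient-threshold rules, fits exponential saturation models of
    intensity against staining time at each tissue depth, derives optimal
    staining times as a function of depth, fits saturating front-propagation
    models for front-forming stains such as phosphotungstic and
    phosphomolybdic acid, and quantifies stain-induced shrinkage from
    segmented cross-sectional areas. Includes a synthetic stained-disc
    phantom generator with closed-form ground truth so every stage of the
    pipeline can be validated without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, ImageAnalysis, Regression
RoxygenNote: 7.3.3
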