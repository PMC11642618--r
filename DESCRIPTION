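Package: finmorph
Title: Standardized Bone Morphometry and Mineral Density Assessment for
    Small Laboratory Fishes
Version: 0.1.0
Authors@R:
    person("finmorph", "developers", email = "finmorph@example.org",
           role = c("aut", "cre"))
Description: Tools for X-ray and micro-computed-tomography (uCT) skeletal
    phenotyping of zebrafish and other small laboratory fishes. Implements
    hydroxyapatite phantom density calibration, region-of-interest
    construction and bone thresholding, volumetric bone mineral density
    (BMD), tissue mineral density (TMD) and bone volume fraction (BV/TV),
    maximal-inscribed-sphere local thickness and the standard vertebral
    measurement suite, an axial-skeleton nomenclature atlas, allometric
    normalization by standard length, acquisition/analysis reporting
    compliance checks, and a synthetic scan generator with analytic ground
    truth so every measurement is testable without real scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
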