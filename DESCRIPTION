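Package: tidemark3d
Title: Three-Dimensional Tidemark Surface Analysis for High-Frequency
    Ultrasound and Micro-CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for reconstructing and comparing the three-dimensional
    tidemark (cartilage-bone interface) surface from paired high-frequency
    ultrasound B-scan stacks and micro-CT volumes. Implements semiautomatic
    tidemark extraction from B-mode stacks (noise-floor estimation from the
    saline region, windowed first-peak detection, crack interpolation),
    micro-CT surface extraction (tilt correction, Otsu binarization, first
    abrupt-change detection, hole interpolation), rigid iterative closest
    point registration with a mean surface-discrepancy statistic, areal
    waviness and roughness indices (Sa/Sq against first- and fifth-order
    polynomial reference surfaces), and en face maximum/average intensity
    projections of the interface slab. Ships a synthetic phantom generator
    producing paired volumes from a known ground-truth surface so the whole
    pipeline can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    rlang,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    RANN,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
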