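Package: crmswitch
Title: Stochastic Modeling of Concentration-Dependent Transcriptional
    Switching at a Homotypic Cis-Regulatory Module
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates WUSCHEL (WUS) transcription-factor binding to the
    five-element cis-regulatory module (CRM) of CLAVATA3 (CLV3) with an
    exact stochastic simulation algorithm.  Models monomer (activating)
    and dimer (repressing) occupancy per cis-element, a residence-time
    limit on transcriptionally active monomers, RNA polymerase II
    recruitment with a refractory gap, and distance-dependent monomer and
    dimer cooperativity.  Includes an exact chemical-master-equation
    oracle for small modules, a genotype grammar covering promoter
    variants (loss-of-binding, affinity, and spacing mutations), a 3D
    half-dome multicellular shoot-apical-meristem model driven by a
    layered WUS gradient, calibration routines for binding rates and the
    concentration scale, synthetic-data generators with known ground
    truth, and a TAAT-core motif-cluster scanner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    yaml,
    jsonlite,
    digest,
    withr,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
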