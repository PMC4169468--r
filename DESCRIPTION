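Package: symbiocomp
Title: Comparative Analysis of Symbiont-Mediated Antiviral Protection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for comparative analyses of heritable
    symbiont phenotypes across host lines. Builds shared-ancestry matrices
    from symbiont phylogenies, quantifies relative symbiont density, viral
    titer and host gene expression from qPCR cycle thresholds with
    efficiency (Pfaffl) correction, derives per-vial protection traits
    (negative log hazard ratios) from mixed-effect proportional-hazards
    survival models, and estimates genetic correlations between traits with
    a Bayesian multi-response mixed model whose between-strain covariance is
    partitioned into phylogenetic and strain-specific components. A
    synthetic-data module generates survival tables, qPCR plates and trees
    with known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    ape,
    multcomp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
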