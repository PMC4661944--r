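Package: ccqtl
Title: Haplotype-Based QTL Mapping for Collaborative Cross Mouse Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative trait locus (QTL) analysis for multiparent
    recombinant inbred panels such as the mouse Collaborative Cross (CC).
    Implements broad-sense heritability and covariate effects from nested
    residual-sum-of-squares model comparisons, weighted founder-haplotype
    association scans with the WSB/EiJ founder as the reference effect,
    empirical genome-wide significance thresholds by line-label permutation,
    regional heritability at mapped loci, merge analysis (variant dosage
    imputation from founder strain distribution patterns) for candidate
    variant nomination, and simulation-based confidence intervals for QTL
    location by residual resampling.  A synthetic-cohort generator emulating
    CC mosaic genomes over the eight founder strains provides ground-truth
    cohorts for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
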