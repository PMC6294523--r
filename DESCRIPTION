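Package: eqtlpower
Title: Simulation and Evaluation of Power, False Discovery Rate and
    Winner's Curse in cis-eQTL Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates linkage-disequilibrium-structured genotypes and
    matched gene expression under a family of generative cis-eQTL models
    (single or multiple causal eSNPs, additive, dominant or recessive
    coding, gamma-distributed or constant effect sizes, normal or
    log-normal noise, co-expressed gene blocks), maps cis-eQTLs by simple
    linear regression of each gene on every SNP within 1 Mb of its
    transcription start site, and evaluates multiple-testing correction
    strategies against the known simulation truth. Supports pooled
    corrections (Bonferroni, Benjamini-Hochberg, Benjamini-Yekutieli,
    Storey-Tibshirani q-values) and hierarchical three-step procedures
    with local corrections including an eigendecomposition-based
    effective-number-of-tests adjustment and exact, beta-approximated or
    adaptive permutation schemes. Includes two-stage (forward/backward)
    conditional analysis of independent eQTL signals and a bootstrap
    correction of Winner's Curse effect-size overestimation with
    shrinkage, out-of-sample and weighted estimators. Scores gene-level
    sensitivity and false discovery rate, top-eSNP causal identification
    and effect-size estimation error over replicated scenario grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    data.table,
    jsonlite,
    yaml,
    vcfR,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
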