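Package: mixepinet
Title: Mixture-Resolved Two-Locus Epistasis Networks for Quantitative Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Resolves cohort heterogeneity in correlated quantitative traits
    (e.g. diastolic and systolic blood pressure) into homogeneous
    subpopulations with a covariate-gated finite mixture of Gaussians fitted
    by EM and selected by sample-size-adjusted BIC and entropy. Within each
    subpopulation it performs an orthogonal (Cockerham-contrast) single- and
    two-locus variance decomposition over a SNP panel, with Hardy-Weinberg
    exact testing, two-locus EM linkage disequilibrium, and Bonferroni-scaled
    significance, then builds gene-gene epistasis networks weighted by
    relative epistatic variance, computes six centrality indices, and
    supports network merge and core-subtraction algebra. A synthetic-data
    module generates genotype/phenotype cohorts with known class structure
    and planted genetic effects for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    nnet,
    nortest,
    igraph,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    xml2
Config/testthat/edition: 3
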