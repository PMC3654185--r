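Package: famlink
Title: Family-Based Linkage and Association Analysis of Quantitative
    Traits and Disease
Version: 1.0.0
Authors@R:
    person("famlink", "developers", email = "famlink@example.org",
           role = c("aut", "cre"))
Description: Tools for the classical family-based gene-mapping chain used in
    studies of quantitative endophenotypes and late-onset disease in nuclear
    families: multipoint identity-by-descent estimation by a hidden Markov
    model over inheritance vectors, univariate and bivariate
    variance-components linkage with LOD curves, an age-adjusted disease
    score from the cumulative incidence of onset, mixed-model and
    GEE-logistic single-variant association with an admixture covariate,
    SNP-conditioned partitioning of the linked-locus variance, pairwise
    linkage disequilibrium with D-prime confidence-interval haplotype
    blocks, greedy tag-SNP selection, EM haplotype frequencies,
    family-aware haplotype dosages and haplotype association.  A
    synthetic-cohort generator reproduces the statistical structure these
    analyses assume, so the whole pipeline is testable without access to
    any private cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lme4,
    survival,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
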