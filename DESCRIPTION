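Package: dqtltools
Title: Germline-Somatic Driver QTL Discovery, Replication and Characterization
Version: 0.1.0
Authors@R:
    person("dqtltools", "maintainers", email = "dqtltools@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering and characterizing driver quantitative
    trait loci (dQTLs): germline SNPs whose genotype is associated with the
    presence of specific somatic driver mutations in tumors. Implements
    per-SNP logistic association scans with covariate adjustment under four
    search-space strategies (risk SNPs, linear windows, chromatin-loop
    spatial regions, enhancer loops), haplotype-block multiple testing using
    the Gabriel block definition, replication testing and random-effects
    (REML) meta-analysis of odds ratios, analytic power via the chi-square
    non-centrality parameter, somatic driver co-occurrence and mutual
    exclusivity statistics, molecular QTL (methylation, expression, protein)
    modeling, ancestry allele-frequency bias tests, p-value distribution
    diagnostics, and a fully seeded synthetic cohort generator so every
    stage is testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    MASS,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
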