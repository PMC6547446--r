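Package: snpsieve
Title: Quality Control and Population-Genetic Analysis of Reduced-Representation SNP Data
Version: 0.1.0
Authors@R: person("snpsieve", "developers", role = c("aut", "cre"),
    email = "snpsieve@example.org")
Description: Caller-agnostic quality control and downstream analysis for
    multi-sample SNP genotype data from reduced-representation sequencing
    (RADseq, GBS, DArTseq and similar). Ingests VCF output from any short
    variant caller, applies a composable per-locus filter suite (allelic
    depth, coverage difference, technical-replicate reproducibility,
    sex-linkage, call rate, minor allele frequency, observed
    heterozygosity, one-SNP-per-locus thinning), estimates genotyping
    error rates from technical replicates, summarises within-population
    diversity, compares genotype concordance across callers, and measures
    between-population divergence with principal coordinates analysis and
    Weir-Cockerham F_ST with bootstrap confidence intervals. Includes a
    Balding-Nichols synthetic dataset generator so the whole pipeline is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
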