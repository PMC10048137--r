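Package: nddtriage
Title: Virtual-Panel Variant Triage for Neurodevelopmental Disorders
Version: 0.1.0
Authors@R: person("NDD", "Triage Maintainers", email = "maintainer@nddtriage.org",
    role = c("aut", "cre"))
Description: Rule-based triage of small variants and copy-number variants for
    gene-panel and virtual-panel diagnosis of neurodevelopmental disorders.
    Implements a stringent primary filter cascade (depth, allele fraction,
    gnomAD allele count, protein-affecting consequence, splice-score ensemble,
    predictor majority voting), a mosaic-aware re-analysis mode with
    cohort-recurrence artifact flagging, a recessive compound-het/homozygous
    extension, dual-caller CNV consensus filtering with reciprocal-overlap
    matching against population SV resources, HPO-based patient subsetting
    into ID/GDD and ASD groups, diagnostic-yield and association statistics,
    a balanced random-forest phenotype profiler with out-of-bag evaluation and
    proximity-based prototype analysis, and a synthetic cohort generator with
    independent truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    methods,
    optparse,
    Rcpp,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
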