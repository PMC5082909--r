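Package: eacnv
Title: Copy-Number Variant Discovery and Prioritization for Isolated Ebstein Anomaly Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for genome-wide copy-number variant (CNV)
    discovery and prioritization in birth-defect cohorts genotyped on SNP
    arrays, modeled on a population-based study of isolated Ebstein anomaly.
    Harmonizes calls from two array CNV callers (PennCNV-style and
    GenomeStudio/cnvPartition-style output), applies rule-based candidate
    selection against reference polymorphism sets (HapMap3 CNPs, CHOP CNV
    blocks, internal controls, DGV), annotates candidates with transcripts and
    candidate-gene lists, triages targeted-sequencing variants by allelic
    balance and population frequency, performs hypergeometric gene-set
    enrichment with enrichment-map clustering, and reproduces the cohort's
    birth-prevalence and demographic statistics. A seeded synthetic-cohort
    generator with planted truth makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    IRanges,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    VariantAnnotation,
    GenomicRanges,
    SummarizedExperiment,
    S4Vectors
Config/testthat/edition: 3
RoxygenNote: 7.3.3
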