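Package: germvar
Title: Ancestry-Stratified Profiling of Germline Cancer-Gene Variation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for cohort-scale analysis of germline variation in
    cancer-associated genes from whole-genome sequencing data. Implements
    a two-stage genotype reliability filter (position-level call rate and
    fractional allele depth, genotype-level minimum allele depth),
    transcript-based consequence annotation by translation of reference
    and alternate coding sequences, supervised admixture estimation
    against a fixed six-population ancestral reference panel with
    threshold-based subpopulation clustering, ancestry-stratified allele
    frequency statistics including detection of major/minor allele flips
    between subpopulations, and per-individual and per-gene variant-load
    profiling. A fully parameterised synthetic-cohort generator with
    truth tables supports end-to-end testing of every stage without
    access to protected genotype data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
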