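Package: mirddr
Title: Genome-Wide miRNA Expression Dynamics in the DNA Damage Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for characterising genome-wide changes in
    microRNA expression after DNA damage from small-RNA sequencing data:
    adapter trimming and exact-identity quantification against a mature-miRNA
    reference, library-size normalisation with count-based differential
    expression (exact Fisher or binomial tests on an MA representation),
    a robustness filter cascade with redundancy resolution and kinetic cluster
    assignment, genomic-context classification of miRNA loci (intragenic or
    intergenic, clustered or single) with category enrichment tests,
    cross-species p53 motif ranking of miRNA regulatory regions by homotypic
    cis-regulatory-module scoring and rank aggregation with order statistics,
    and preranked gene-set enrichment analysis calling direct p53 targets.
    Includes a fully seeded synthetic-data generator that emulates the study
    design (cell lines, time courses, technical replicates, planted effects
    and planted motif clusters) for oracle-based validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    knitr
Config/testthat/edition: 3
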