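Package: premotif
Title: Mutation-Selection Simulation and Motif Statistics for the Origins
    of Splicing Enhancers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to study how context-dependent mutational bias and
    protein-level purifying selection shape short sequence motifs. Implements
    heptamer-context relative mutation rate (ERM) arithmetic, a circular
    mutation-selection sequence simulator with an exact small-state-space
    oracle, exon/intron hexamer enrichment and splice-site mutability
    profiles, amino-acid-pair statistics linking enhancer activity to the
    protein code, splicing-assay allelic-ratio statistics, and synthetic-data
    generators that emulate every input the analyses consume.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    Matrix,
    methods,
    Rcpp,
    rtracklayer,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
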