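Package: microbusco
Title: Completeness Assessment of Genomic Data with Universal Single-Copy Orthologs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assesses the completeness of genome assemblies, annotated gene
    sets, and transcriptomes in terms of expected gene content, using
    lineage-specific sets of near-universal single-copy orthologs. Builds
    profile hidden Markov models from ortholog alignments, delineates
    ortholog sets from an orthology table with per-ortholog score and
    length cutoffs, classifies every ortholog in a target data set as
    complete single-copy, complete duplicated, fragmented, or missing,
    exports complete gene models for ab initio gene-predictor training,
    and extracts shared single-copy markers into a trimmed, partitioned
    supermatrix for phylogenomics. A seeded simulator generates ortholog
    lineages and target sequence sets with planted ground truth so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    ape,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
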