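Package: lncTempo
Title: Temporal lncRNA Identification, Co-Expression Modules and Target
    Networks Across Staged Development
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for stage-resolved long non-coding RNA
    (lncRNA) analysis in bulk RNA-seq designs: identification of lncRNA
    candidates from assembled transcripts (length, exon-count and
    coding-potential consensus filters), positional classification into
    lincRNA, antisense and intronic classes, cross-species conservation
    contrasts from homology-hit tables, stage-wise differential
    expression over a 7-stage x 3-replicate design, a from-scratch
    signed weighted co-expression network (soft threshold, topological
    overlap, average-linkage tree cut, module eigengenes,
    module-stage statistics and early/late/stage-specific temporal
    classification), cis-window and co-expression target prediction
    with hub extraction from the bipartite lncRNA-mRNA network, and
    hypergeometric over-representation with Benjamini-Hochberg
    correction. A synthetic-data generator plants known temporal
    modules so that every stage of the pipeline is testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    jsonlite,
    mclust
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
biocViews: Transcriptomics, GeneExpression, Network, Clustering,
    DifferentialExpression, FunctionalPrediction
Config/testthat/edition: 3
RoxygenNote: 7.3.3
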