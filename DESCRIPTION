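Package: amplipipe
Title: Quality-Sorted OTU Analysis of 16S rRNA V1-V2 Pyrosequencing Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end analysis of barcoded 454-style 16S rRNA V1-V2 amplicon
    surveys: demultiplexing, primer checking with a long-read exception,
    mean-quality filtering, reference-based chimera flagging and taxonomy
    assignment, rarefaction, quality-sorted greedy OTU clustering at 96
    percent identity, alpha-diversity estimation (Shannon, Simpson, inverse
    Simpson, Pielou, Chao1, ACE, Fisher's alpha), weighted and unweighted
    UniFrac with principal-coordinate and dendrogram ordination,
    group-comparison statistics with Benjamini-Hochberg correction,
    biomarker-abundance correlation analysis, and qPCR concordance. Includes
    a seeded synthetic-study generator (reference database, community
    profiles, error- and chimera-bearing reads, biomarker and qPCR panels)
    with ground-truth manifests so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    ape,
    phangorn,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    phyloseq,
    jsonlite,
    optparse
Config/testthat/edition: 3
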