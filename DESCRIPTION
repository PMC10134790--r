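Package: soloscan
Title: Detection, Clustering, and Classification of LuxR Solo Regulators
    in Annotated Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An in silico survey pipeline for quorum-sensing LuxR "solo"
    (orphan) regulators in proteobacterial genomes. Identifies LuxR-family
    proteins by their autoinducer-binding Pfam domain and calls them solos
    when no LuxI-family acyl-homoserine-lactone synthase gene lies within a
    configurable gene-rank neighborhood; classifies luxI/luxR pair
    topologies; clusters solo proteins by greedy incremental alignment at
    identity and coverage thresholds; fingerprints large clusters by the
    Pfam content of their genomic neighborhoods, embeds the fingerprints in
    three dimensions, and density-clusters them into subgroups; scores
    TraR-anchored conserved residues and diagnostic motifs to suggest
    candidate ligand classes; and summarizes cluster representatives as a
    neighbor-joining tree in annotated Newick. Ships a seeded generator of
    synthetic annotated genomes with planted ground truth so the whole
    pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    rtracklayer,
    ape,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    igraph,
    optparse
Config/testthat/edition: 3
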