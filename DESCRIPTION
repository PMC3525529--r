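Package: deflevol
Title: Comparative Genomics of Lineage-Specific Defensin-Like Gene Clusters
Version: 0.1.0
Authors@R:
    person("Aiko", "Tanaka", email = "aiko.tanaka@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering and characterising species-specific
    clusters of defensin-like (DEFL) peptide genes between two closely
    related plant genomes. Implements bootstrap-supported paralog-group
    detection on neighbor-joining trees, cross-species reciprocal-monophyly
    classification, reciprocal-best-hit orthology, tandem-array and
    flanking-anchor synteny analysis with duplication-history inference,
    Nei-Gojobori (1986) dN/dS, the McDonald-Kreitman test, and
    loss-of-function classification of cysteine-rich peptides, together
    with a gene-family evolution simulator that provides ground truth for
    every stage of the pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
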