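Package: mirtrigo
Title: Tri-Partite Functional Enrichment Analysis for miRNA Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Functional enrichment analysis of microRNA (miRNA) clusters
    over the full tri-partite network topology linking miRNAs, predicted
    target genes, and Gene Ontology terms.  Implements three hypergeometric
    enrichment measures -- the classical target gene-centric test (rho) and
    the target link-centric (tau) and miRNA-centric (mu) tests that account
    for targeting multiplicity and cooperativity -- together with Fisher
    combination of their p-values, rank-normalized top-n term sets, and
    evaluation of term sets by Information Content and Resnik semantic
    similarity density.  Ships readers for OBO ontologies, GAF gene
    annotations and miRNA-target pair tables with prediction-algorithm
    votes, plus a seeded synthetic scenario generator for end-to-end
    testing without external databases.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
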