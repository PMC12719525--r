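Package: swarmlink
Title: Protein Swarm Co-Citation Spectra and Confidence-Cut Association Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds protein "swarms" (groups of at most five proteins) from
    overlaps between tissue proteomes and biological-process gene sets,
    counts their co-citation frequencies with diseases, immune functions and
    microRNAs in an annotated abstract corpus ("information spectra"),
    clusters the spectra hierarchically with cluster-similarity-confidence
    (CCSV) dendrogram cuts into protein swarm associations (PSAs), tests
    gene-set overlap enrichment with hypergeometric statistics and
    Benjamini-Hochberg FDR control, and links microRNA clusters to PSAs.
    Ships a synthetic-corpus generator with planted block structure so the
    whole analysis can be exercised and benchmarked against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Matrix,
    igraph,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
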