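Package: pathmapr
Title: Cross-Database Pathway Gene-Set Comparison, Enrichment and Mapping Curation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates pathway gene-set collections from multiple databases
    (read from GMT files) and compares them: gene-coverage partitions across
    resources, pathway-size and gene-promiscuity summaries, pathway similarity
    via the Szymkiewicz-Simpson overlap coefficient and Levenshtein-based
    lexical similarity, Fisher's exact-test over-representation analysis with
    Benjamini-Yekutieli false-discovery-rate control and rule-based filtering,
    similarity-network construction with edge-weight thresholding and module
    detection, average-linkage hierarchical clustering of gene sets, and a
    curatable catalog of typed inter-database pathway mappings (equivalentTo,
    isPartOf) with similarity-based suggestion, voting-based acceptance,
    consensus merging and hierarchy inference. A deterministic synthetic-data
    generator plants equivalent and hierarchical pathways with controllable
    noise to benchmark mapping recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    rlang,
    igraph,
    ape,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
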