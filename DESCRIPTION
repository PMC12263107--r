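Package: pm3miner
Title: Extraction of ACMG/AMP PM3 Evidence from Full-Text Publications
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts ACMG/AMP PM3-relevant evidence (variant mentions and in
    trans partner variants) from a single full-text publication in PMC BioC
    XML. A query variant in HGVS coding notation is expanded into all of its
    textual representations (DNA notation, protein change, one-letter
    shorthand), compiled into a cascade of progressively more tolerant match
    patterns, and searched for in both the prose (via fixed-length overlapping
    chunks and a variant-specific retriever) and the tables (via an embedded
    relational store with position-guided queries and a digit-boundary
    post-filter). Rows carrying the query variant are expanded to same-patient
    neighbour rows to recover in trans candidates. A deterministic mock
    completion backend makes the whole pipeline testable offline; an HTTP
    adapter for a local model server is provided. Includes a benchmark harness
    with shuffled-negative sampling and a seeded generator of synthetic
    publications with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
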