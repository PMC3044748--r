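Package: sbpkb
Title: Knowledgebase Construction and Query Refinement for Standard Biological Parts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Transforms Registry-style tables of standard biological parts
    (BioBricks) and their positional sequence features into an RDF knowledge
    graph organised by an automatically generated class hierarchy derived from
    the Registry category vocabulary. Provides Turtle and RDF/XML
    serialization, a SPARQL subset engine, and a named query bank implementing
    a promoter query-refinement workflow: all promoters, cleaned promoters
    (sequence present, not deleted), sigma70 promoters, dual-regulated
    promoters, and dual-regulated promoters carrying annotated operator
    sites. Includes seeded synthetic-fixture generators so the full
    transform-and-query pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    digest,
    dplyr,
    jsonlite,
    optparse,
    stats,
    tibble,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
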