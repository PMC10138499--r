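Package: biograph
Title: Linking and Querying Heterogeneous Biological Metadata as a Knowledge Graph
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A generic knowledge-graph data model and query system for
    biological metadata integrated from heterogeneous datasets. Biological
    entities (genes, proteins, diseases, antigens, epitopes, organisms),
    their identifiers and non-identifier metadata become content-addressed
    graph nodes linked by typed relations, so identical records from
    different sources deduplicate automatically. Includes an embedded
    transactional graph store with a catalog index (prefix-tree keyword
    search, import logging), a JSON pattern-query language whose matches
    are decomposed into linear edge-disjoint paths, importers for five
    dataset dialects (DisProt, HGNC, DisGeNET, IEDB, Tantigen styles) with
    a deterministic fixture generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
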