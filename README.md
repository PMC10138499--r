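# biograph

Biological metadata are scattered across databases with incompatible
schemas: protein-disorder annotations, gene nomenclature, gene–disease
association scores, tumor antigens and their epitopes each live in their
own silo, naming the same entities with different identifiers. Questions
that join those silos — *which tumor-antigen genes are associated with a
disease and transcribed into highly disordered proteins?* — cannot be
asked of any single source. **biograph** integrates such metadata into
one queryable knowledge graph, for bioinformaticians who want
cross-database questions answered locally and offline.

## The model

Four content-addressed object kinds make up the graph:

| Kind | Keyed by | Attached via |
|---|---|---|
| entity | (type, primary identifier), e.g. `gene` + `CDKN1A` | — |
| identifier | kind ∈ {name, url, id}, title, value | `HAS_ID` |
| data | dataset source label + scalar payload | `HAS_DATA` |
| relation | label, endpoints, properties | edge itself |

Entity–entity edges use an open vocabulary with six base labels: `IS`,
`IS_INSTANCE`, `IS_VARIANT`, `FROM`, `CONTAINS`, `RELATED_WITH` (e.g.
*gene IS antigen*, *protein FROM gene*, *antigen CONTAINS epitope*, *gene
RELATED_WITH disease* carrying `score`). Every object's ID is the SHA-256
of a canonical serialization of its content, so identical records from
different imports collapse onto one node — entity resolution falls out of
hashing, with no merge heuristics:

```r
bg_id(bg_entity("gene", "CDKN1A"))
#> "3e82639b85d85d3f1df28bb2e895c754b27fdc68edf6574b2f04c13ceeb6cb68"
```

Around the model sit an embedded transactional graph store with
JSON-lines snapshots, a catalog index (entry/import logs plus prefix-tree
keyword search over identifiers and descriptions), a JSON pattern-query
language whose matches are decomposed into linear edge-disjoint paths,
importers for five dataset dialects (DisProt, HGNC, DisGeNET, IEDB and
Tantigen styles) with a deterministic fixture generator, and a CLI
(`inst/exec/biograph`).

## Worked example

The bundled `worked_example` fixtures reconstruct a five-source network
around the gene CDKN1A. Importing them and running the example
cross-dataset query:

```r
library(biograph)

db <- bg_build_worked_example()
db
#> <biograph db: 5 entities, 6 identifiers, 5 data objects, 15 relations>

matches <- bg_execute(db, bg_example_query())
vapply(matches[[1]]$binding, function(i) bg_get(db, i)$primary_identifier, "")
#>           d           g           p           a           e
#>  "C0038356"    "CDKN1A"    "P38936"  "Ag002102" "FAWERVRGL"

length(bg_decompose_paths(db, matches[[1]]))
#> [1] 2
```

The five entities are the gene (CDKN1A), its protein (UniProt P38936,
also DisProt DP00016, disorder content 0.9), a disease (UMLS C0038356,
association score 0.9), a tumor antigen (Ag002102) and its epitope
(FAWERVRGL); the six identifier objects are the gene name and NCBI ID,
both protein accessions, the disease CUI and the antigen accession. The
query — association score ≥ 0.5, disorder content ≥ 0.9, gene IS antigen,
antigen CONTAINS epitope — binds all five entities in one match. Because
the matched subgraph branches at the gene (degree 3), it is reported as
two linear edge-disjoint paths:

```r
bg_export_results(db, matches, "results.csv", format = "csv")
#> "match_index","path_index","node_1","relation_1","node_2","relation_2","node_3"
#> "1","1","P38936","FROM","CDKN1A","RELATED_WITH","C0038356"
#> "1","2","CDKN1A","IS","Ag002102","CONTAINS","FAWERVRGL"
```

Keyword search runs on the catalog's prefix trees, e.g.
`bg_keyword_search(db, "pneumonia", entity_type = "disease")` after
importing a DisGeNET-style row describing a pneumonia disease, or
`biograph search --db store.jsonl --keyword pneu --prefix` from the
shell.

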