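---
title: "The biograph data model: linking and querying heterogeneous biological metadata"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The biograph data model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biograph)
```

## The problem

Biological metadata live in isolated silos with incompatible schemas: a
disorder database describes proteins, a nomenclature registry describes
genes, a disease-association resource scores gene–disease links, and
immunology resources catalogue antigens and their epitopes. The same
biological entity appears in several of them under different identifiers,
and questions that span sources — *which tumor-antigen genes are linked to
a disease and transcribed into highly disordered proteins?* — cannot be
asked of any single database. biograph integrates such metadata into one
knowledge graph built from four addressable kinds of object:

* **entity objects** — one biological (or contextual) thing, keyed by a
  lowercase type (`gene`, `protein`, `disease`, `antigen`, `epitope`,
  `organism`, ...) and a *primary identifier*, the identifier most widely
  shared across datasets (gene symbol, UniProt accession, UMLS CUI, ...);
* **identifier objects** — `(kind, title, value)` records of every
  identifier an entity carries, attached by `HAS_ID` edges and shareable
  among entities;
* **data objects** — non-identifier metadata (disorder content,
  chromosome location, annotations) bundled with the label of the dataset
  they came from, attached by `HAS_DATA` edges;
* **relations** — labeled, directed, property-carrying edges. Six base
  labels connect entities (`IS`, `IS_INSTANCE`, `IS_VARIANT`, `FROM`,
  `CONTAINS`, `RELATED_WITH`); the vocabulary is open for higher-level
  schemas.

The model stores metadata, not primary data: a gene's sequence stays in
its home database, reachable through the identifiers the graph holds.

## Content addressing

Every object's ID is the SHA-256 hash of a canonical serialization of its
content: a kind tag plus its fields with keys sorted lexicographically,
UTF-8, no insignificant whitespace (`bg_serialize()` documents the exact
byte format). Three normalization rules make deduplication robust across
dialects: numbers serialize in shortest round-trip decimal form (0.9 and
0.90 hash equally), relation labels are upper-cased with spaces mapped to
underscores, and entity types are lower-cased. The payoff is automatic
entity resolution: when two importers mention gene CDKN1A they
necessarily produce the same 64-hex ID and the records collapse onto one
node — no linkage heuristics, no merge step.

```{r}
bg_id(bg_entity("gene", "CDKN1A"))
```

## Store, transactions, catalog

The graph lives in an embedded in-memory store persisted as a JSON-lines
snapshot (gzip accepted by extension); the store implements a small
adapter contract for which `bg_neo4j_adapter()` sketches the
server-backed alternative. All writes go through a single-writer
transaction that covers the graph *and* the catalog index together:
pending writes are invisible until commit, and rollback restores both to
the pre-transaction state, so an aborted import leaves no partial rows
anywhere. Recovery after a crash *between* the two stores cannot arise
here because both commit under one transaction object; a true two-phase
protocol for separate backends is out of scope.

The catalog mirrors a relational side-database with four indexers: an
entry log (one row per object per import), an import log (source, times,
inserted/skipped counts), and two keyword indexes held in prefix trees —
identifier values and free-text descriptions. Tokenization lowercases,
splits on non-alphanumeric runs and keeps tokens of length ≥ 2; the full
lowercased identifier value is additionally indexed verbatim so exact ID
lookup (`C0038356`) always works alongside word search (`pneumonia`).
Prefix trees serve exact and prefix matching; infix search is
deliberately unsupported, as a trie cannot serve it directly, and no
ranking or fuzzy matching is attempted.

## The query language and matcher

Queries are JSON documents with exactly two segments: `match` (aliases
with entity types, and the relations between them) and `params`
(conditions on aliases). Condition targets are `primary_id`,
`identifier`, `data.<source>.<key>` and, on edges, `prop.<key>`;
operators are `eq, ne, gt, gte, lt, lte, contains`. Both strict and
non-strict inequalities exist because use cases phrase thresholds both
ways ("greater than 0.5" vs "0.5 and greater"); the shipped example query
uses `gte`. Matching semantics are **injective** on entity nodes —
distinct aliases bind distinct entities, isomorphism-style — because a
drawn pattern with two boxes means two different biological things; the
alternative (homomorphic) reading is noted as a design choice that tests
pin down. Pattern edges must map to distinct stored relations; direction
is respected by default (`FROM`, `CONTAINS` and friends are stored
directed) with an explicit `"any"` override.

The matcher is a backtracking search that binds the most-constrained
alias first and checks edge feasibility as soon as both endpoints are
bound. Results are sorted by their binding tuple, so identical runs
produce byte-identical exports. Missing attributes make a condition
false rather than raising, and an ordering comparison against a
non-numeric stored value is false with a logged warning — queries over
messy metadata should filter, not crash.

## Linear disjoint paths

Matched patterns are usually branching, so each match is decomposed into
linear, pairwise edge-disjoint paths whose union covers the matched edges
exactly. The algorithm peels maximal trails: start at the odd-degree
vertex with the smallest ID (ties and all edge choices break toward the
smallest ObjectID, which makes the decomposition deterministic), walk
unused edges until stuck, repeat. A parity argument shows each peel
consumes two odd-degree vertices, so for tree-shaped matches the path
count is the minimum possible, half the number of odd-degree vertices.
Cyclic matched subgraphs are accepted: the cover is still edge-disjoint
and exact, without the tree minimality guarantee. In the worked example
below the gene has degree 3, four vertices have odd degree, and the match
splits into exactly 2 paths.

## Importers and the worked example

Importers speak a five-method contract — `begin_import`, `map_entity`,
`map_identifier`/`map_data`, `map_relation`, `finish_import` — and every
mapped object flows through content addressing, dedup, the graph store
and the catalog in one transaction. Field names are read from small
mapping configs (`inst/extdata/mappings/`) because real releases rename
columns. Per-dialect primary identifiers: gene → symbol, protein →
UniProt accession, disease → UMLS CUI, antigen → accession, epitope →
amino-acid sequence, organism → taxon. A structurally broken file
(missing required column) aborts the import with rollback; a bad record
(unparsable score, missing symbol) is skipped with a warning, and
`read = produced-from + skipped` is conserved in the import record.

The fixture generator emulates the five dialects offline. Its
`worked_example` dialect deterministically reconstructs the
five-source example network — gene CDKN1A, protein P38936 (DisProt
DP00016, disorder content 0.9), disease C0038356 (association score
0.9), antigen Ag002102, epitope FAWERVRGL — which imports to exactly 5
entities and 6 identifier objects:

```{r}
db <- bg_build_worked_example()
unlist(bg_stats(db)[c("entities", "identifiers", "relations")])
matches <- bg_execute(db, bg_example_query())
vapply(matches[[1]]$binding, function(i) bg_get(db, i)$primary_identifier, "")
length(bg_decompose_paths(db, matches[[1]]))
```

Randomized dialect fixtures draw entity names from shared pools so the
same genes, proteins, antigens and epitopes recur across files and
cross-dataset joins are exercised; the `overlap` parameter (default 0.3)
sets how aggressively the pools are shrunk. Scores and disorder contents
are uniform on \[0, 1\], which emulates the *shape* of the real data
(shared keys, scored edges, mixed formats) but none of its biology:
passing tests show the machinery is correct, not that any particular
biological association is reproduced. Real-scale behavior (millions of
objects) is likewise out of scope for the test fixtures; suite problem
sizes were chosen as the smallest that still exercise every code path —
stores of up to 40 entities against a brute-force matcher oracle, trees
of up to 12 edges against an exact minimum-cover search, about a
thousand randomized keyword probes and hash invariance checks.

## Numerical and degenerate-input choices

* Doubles serialize for hashing in shortest round-trip decimal form;
  non-finite payload numbers are rejected at serialization.
* Numeric conditions compare as doubles with exact `==` for `eq`; string
  comparisons (`eq`, `ne`, `contains`) are case-insensitive.
* Empty stores, empty result sets and punctuation-only descriptions are
  all valid inputs that produce empty outputs, never errors.
* Disorder content outside \[0, 1\] is stored as-is with a warning — the
  importer does not silently repair source data.
* The import log records wall-clock timestamps; they are the only
  non-deterministic bytes in a snapshot, and exports contain none.

## Known limitations

The embedded store is single-writer and memory-bound; the documented
adapter contract is where a server-backed graph database would plug in,
and the bundled adapter for it is deliberately a stub. Keyword search has
no ranking and no substring mode. The query planner is only
most-constrained-first ordering — patterns are small, stores are local.
No RDF export, no ontology alignment, and no natural-language querying:
the JSON pattern language plus keyword search is the whole query surface.
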