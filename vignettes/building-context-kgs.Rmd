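---
title: "Building context-specific knowledge graphs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building context-specific knowledge graphs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ContextKG)
```

## The problem

Most biomedical knowledge-graph pipelines either warehouse whole
databases locally (expensive to store, quickly stale) or leave the
integration burden to the researcher. ContextKG takes the federated,
modular-query route: a small graph is assembled on demand around the
user's own entities, querying each selected data source independently
and keeping per-edge provenance so the result remains auditable.

The data model is deliberately closed: 18 node types and 10 directed
relations. A closed vocabulary is what makes the downstream machinery —
typed serialization, SHACL shape generation, type-compatible negative
sampling — total functions rather than best-effort heuristics. Proteins
are intentionally not distinct nodes; protein-level assertions fold onto
the coding gene, which keeps gene-centric inputs (the common case for
DEA tables) connected to protein-level resources without a second
identifier layer.

## Harmonization

All inputs reduce to records of (raw identifier, optional declared
namespace, entity kind, optional DEA statistics). Identifiers written as
`NS:accession` CURIEs carry their namespace; bare tokens are matched
against the mapping table in any source namespace.

Mapping follows **one direct hop plus one pivot hop** through a hub
namespace (default `HGNC`, the natural hub for human gene symbols).
Deeper transitive closure is off by default: every additional hop
multiplies the chance of spurious chains through promiscuous
identifiers, and two hops already connect symbol-keyed inputs to any
namespace the mapping table covers. When one source identifier reaches
several canonical accessions, the lexicographically first becomes the
canonical key — an arbitrary but deterministic tie-break, recorded in
the table's provenance string; the alternatives stay available as
cross-references. Duplicate inputs merging onto one canonical key are
accepted silently only when their DEA statistics agree exactly;
conflicting statistics raise an error, because silently averaging (or
overwriting) evidence would corrupt the one quantitative signal the
graph carries.

Canonical namespaces default to Entrez for genes, UMLS for diseases and
PubChem CIDs for compounds, overridable per entity kind.

## Annotation and the source catalog

The catalog registers 15 sources with their query dialects; five ship
with concrete request builders and parsers (DisGeNET and MINERVA and
STRING over REST, OpenTargets over GraphQL, Bgee over SPARQL), so every
dialect in the catalog is exercised by at least one real adapter. The
remaining ten are contract-complete stubs: selectable, typed, but
refused at query time.

Each source's contribution is fixed as a set of (subject type, relation,
object type) categories. The assignment was chosen so that the
four-source context recipe — DisGeNET, OpenTargets, MINERVA, STRING —
collapses to exactly five node-type pair categories (gene–disease,
gene–compound, disease–compound, gene–pathway, gene–gene). This forces
two choices worth recording: MINERVA contributes only gene–pathway
membership (its compound support is registered as a supported entity but
maps to no edge category), and the Gene Ontology `part_of` categories
live under g:Profiler rather than OpenTargets. Both keep the
four-source collapse at five categories while leaving GO annotation
reachable through a different selection.

Batching is 25 identifiers per request in input order — large enough to
amortize transport overhead, small enough that a single failed batch
loses little. Every batch is stamped with query metadata (source name
and version, retrieval date, input and result counts, wall-clock
duration). Durations are recorded but never asserted in tests, being
hardware-dependent. Sources run independently: a transport failure
becomes a failure record in the run report, never an abort of the other
sources.

Rows whose subject is not an input entity (a drug acting on an input
gene, from OpenTargets' known-drugs view) carry their own subject type
and label, so the builder can create the node; an unknown subject
without that self-description is an integrity error.

## The fixture transport

`fixtureFetcher(seed, density)` synthesizes dialect-correct responses:
REST JSON for DisGeNET/MINERVA/STRING shapes, a GraphQL result document
for OpenTargets, SPARQL results JSON for Bgee. Each (entity, candidate)
pair from small fixed pools (3 diseases, 3 compounds, 3 pathways, 3
anatomical entities; STRING pairs within the batch) is included with
probability `density` under a hash stream keyed by (seed, source,
entity, candidate) — no global RNG state, so identical inputs give
byte-identical responses and per-source results are independent of
which other sources run.

What this emulates: response envelopes, identifier cross-referencing
(EFO→UMLS, ChEMBL→PubChem), score fields, mechanism-of-action strings,
expression levels and developmental stages. What it deliberately does
not emulate: realistic score distributions, the heavy tail of node
degrees, pagination, rate limits, schema drift over time, and the sheer
scale of real sources. Passing tests therefore demonstrate the
correctness of the plumbing — harmonization, merging, provenance,
serialization — not biological validity of any edge, and graph-level
statistics from fixture runs carry no scientific meaning.

## Graph construction

Edge identity is the (subject, relation, object) triple. The same
assertion from several sources merges into one edge whose provenance
accumulates one entry per source run; this is what makes build order
irrelevant (node keys, edge triples and provenance sets are invariant
under permutation of annotation rows, which the test suite checks by
permutation). Node attribute collisions resolve last-writer-wins with a
warning — except DEA statistics, which raise. Self-loops are allowed
only for `interacts_with` (a protein complexing with itself); any other
reflexive assertion is flagged by `validateGraph()`.

All output orderings (node keys, edge triples, provenance rows,
attribute names, serialized triples) are canonicalized with
locale-independent radix sorting, which is what makes repeated exports
byte-identical.

Degenerate inputs are first-class: an empty input yields an empty but
valid graph, an empty source selection yields input nodes with zero
edges, and every error path carries a typed condition class
(`ckg_*_error`) so callers can branch on failure kinds.

## Serialization

Cytoscape export uses the plain `.cyjs` elements document (nodes/edges
arrays) rather than the CX stream — the simplest stable dialect; a CX
exporter could be added behind the same surface. GraphML declares every
attribute key once with a type; scalar attributes map to native GraphML
types (doubles serialized at 17 significant digits so they round-trip
exactly), vector-valued attributes are JSON-encoded with the decoding
rule carried in the key id. `fromGraphml(toGraphml(g))` is the identity
on nodes and edges, verified property-style on 100 generated graphs.

RDF uses SIO, RO, BFO and SKOS terms from a shipped, versioned mapping
file (`inst/extdata/rdf_mapping.json`) that is total over both
vocabularies. `associated_with` edges are reified as first-class
association nodes (`sio:has_part` to both participants, one provenance
record node per entry) — matching how gene–disease associations are
modelled as nodes in RDF views of such graphs — while all other
relations stay direct triples with standard RDF reification carrying
provenance. Numeric attributes use the SIO measurement-value pattern.
The triple count is therefore an affine function of
(nodes, edges, cross-references, attribute elements, provenance
entries); tests verify it against an independent per-element enumerator.

SHACL shapes are generated for exactly the node types instantiated in a
graph, never all 18, with property constraints for the predicates
actually used; `rdfs:label` carries `minCount 1`. The package includes a
validator for precisely this SHACL-core subset (class-targeted node
shapes, `sh:path`/`sh:minCount`), used to check self-conformance of
every export. It is not a general SHACL engine, and the structural
checks used for SPARQL/GraphQL payloads in the test suite are likewise
structural (balanced braces, required clauses), not full grammars — a
known limitation.

ShEx output is not generated; one constraint language was chosen and
SHACL has the broader triple-store support.

## Analysis

Subgraph extraction expands hop neighborhoods over *undirected* edges —
a tissue or disease context includes both what a gene regulates and
what regulates it — while preserving direction in the output; type and
relation filters apply after expansion. Results are validated graphs
with provenance intact, and the node set is checked against a
brute-force BFS oracle in tests.

Training-set export emits one positive per edge and samples negatives
uniformly from type-compatible non-edges, where compatibility is the
catalog's own incidence — negatives like "compound part_of disease"
that no source could ever assert would be trivially separable and
useless for training. No published negative-sampling scheme exists for
this setting; uniform type-compatible sampling is this package's
choice. Sampling ranks candidates by a seeded hash, so it is exactly
reproducible and never duplicates a positive; requesting more negatives
than free combinations is an explicit infeasibility error rather than a
silent truncation.

## Pipeline and configuration

`runPipeline()` chains the four stages, writes all requested exports
plus summary, unmapped and failure reports, and embeds the full query
metadata list in `report.json` — the reproducibility contract: a report
plus the config and seed regenerate the exports byte-for-byte. Run
configs are YAML (comment-friendly, human-writable, parsed with the
yaml package); CLI flags mirror config keys and win on conflict.

## Problem sizes and known limitations

The shipped property suites run at deliberately small scale: 100 graphs
of up to ~15 nodes for GraphML round-trips, 25 for SHACL
self-conformance, 20 for triple-count law checks, graphs of up to 50
nodes for the BFS oracle, 20 seeds for sampling disjointness, and a
10-gene end-to-end recipe. These sizes exercise every code path
(multi-provenance edges, vector attributes, all five adapters) while
keeping the whole suite under a minute; nothing in the implementation
is specific to these sizes.

Limitations worth knowing: live transports are contracts only (no
retry/backoff tuning, no authentication); identifier mapping is exact,
never fuzzy; there is no ontology-aware reasoning (no transitive
closure over `part_of`, no subsumption); cross-species comparison and
embedding-based prediction are out of scope; and the ten stub sources
parse nothing until someone writes their adapters.
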