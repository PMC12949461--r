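# ContextKG

Build context-specific, provenance-tracked biomedical knowledge graphs
directly from the entity lists a study produces — a set of genes or
proteins, a set of metabolites or compounds, or a differential-expression
(DEA) result table — instead of warehousing entire databases locally.

The package is aimed at systems-biology and translational researchers who
want a small, question-specific graph ("which diseases, drugs and pathways
surround my differentially expressed genes?") that stays reproducible:
every edge records which source asserted it, in which version, on which
date, and every annotator run is stamped with query metadata.

## The model

The pipeline has four stages:

1. **Harmonize** — input identifiers are mapped onto canonical namespaces
   (genes → Entrez, diseases → UMLS, compounds → PubChem CIDs) through a
   pluggable mapping table or service, keeping all reachable
   cross-references. Mapping follows one direct hop plus one pivot hop
   through a configurable hub namespace (default HGNC); one-to-many
   mappings resolve deterministically to the lexicographically first
   target, the rest retained as cross-references. DEA effect sizes and
   p-values ride along and become gene-node attributes.
2. **Annotate** — a catalog of 15 registered data sources (SPARQL, REST
   API, GraphQL and tabular-download dialects) is queried per source
   through an injectable transport. Five adapters are concrete
   (DisGeNET, OpenTargets, MINERVA, STRING, Bgee); a deterministic
   fixture transport synthesizes dialect-correct responses for offline
   work and testing. Failures of one source never abort the others.
3. **Build** — typed assertions merge into one property graph with a
   closed vocabulary of 18 node types and 10 directed relations. Edge
   identity is the (subject, relation, object) triple; repeated
   assertions accumulate provenance entries instead of creating parallel
   edges. Context nodes (e.g. a disease anchoring the study) can be
   injected with curated links.
4. **Analyze / serialize** — summaries, hop-bounded context subgraphs,
   labelled triple sets for link prediction, and three export formats:
   Cytoscape JSON (`.cyjs`), GraphML (round-trippable, Neo4j/APOC
   friendly) and RDF Turtle with SIO/RO/BFO vocabulary plus
   auto-generated SHACL shapes for exactly the classes the graph uses.

## Worked example

```r
library(ContextKG)

dea     <- demoDeaTable(10)                      # synthetic DEA table
records <- parseInput(dea, "dea_table")
table   <- mapIdentifiers(records, demoMappingTable())
table
#> HarmonizedTable: 10 mapped, 0 unmapped (mapping: demo mapping table ...)
#>   keys: ENTREZ:3429, ENTREZ:3437, ENTREZ:3627, ENTREZ:4938, ENTREZ:9636 ...

ann <- annotateTable(table,
                     c("DisGeNET", "OpenTargets", "MINERVA", "STRING"),
                     fixtureFetcher(seed = 7, density = 0.4))
graph <- buildGraph(table, ann$rows, ann$metadata)
graph <- addContextNode(graph, "UMLS:C5433293", "disease", "Long COVID-19",
  links = data.frame(entity_key = harmonizedRows(table)$canonical_key[1:3],
                     relation = "associated_with"),
  provenance_tag = "literature")
graph
#> PropertyGraph: 23 nodes, 78 edges
#>   node types: compound(3), disease(4), gene(10), pathway(6)
#>   relations: activates(7), associated_with(30), inhibits(9),
#>              interacts_with(5), part_of(20), treats(7)
```

The 10 input genes were all harmonized to Entrez keys; the four selected
sources contributed disease associations, drug regulation/treatment
edges, pathway memberships and gene–gene interactions (exactly the five
node-pair edge categories this source selection can produce), and the
injected long-COVID disease node anchors the context. From here:

```r
summarizeGraph(graph)
#> GraphSummary: 23 nodes, 78 edges, 0 unannotated inputs
toCytoscapeJson(graph, "graph.cyjs")
toGraphml(graph, "graph.graphml")
writeTurtle(toRdf(graph), "graph.ttl")
head(exportTrainingTriples(graph, negative_ratio = 1, seed = 7), 3)
#>          head        relation          tail label
#> 1 ENTREZ:3429 associated_with UMLS:C0010200     1
#> 2 ENTREZ:3429 associated_with UMLS:C0015672     1
#> 3 ENTREZ:3429 associated_with UMLS:C0231528     1
```

The same run as a single command (`inst/scripts/contextkg.R`):

```sh
Rscript inst/scripts/contextkg.R --config run.yaml --seed 7
```

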