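test_that("an empty table with no rows builds an empty graph", {
  tab <- mapIdentifiers(parseInput(character(), "gene_list"),
                        ContextKG:::emptyMappings())
  g <- buildGraph(tab)
  expect_equal(nrow(graphNodes(g)), 0L)
  expect_equal(nrow(graphEdges(g)), 0L)
  expect_equal(nrow(validateGraph(g)), 0L)
})

test_that("edges merge by triple with provenance accumulation", {
  tab <- toyHarmonized()
  meta <- toyMetadata(c("DisGeNET#1", "OpenTargets#1"),
                      c("DisGeNET", "OpenTargets"))
  # two different gene-disease triples -> 2 edges, 1 provenance each
  rows <- rbind(
    toyRow("ENTREZ:7157", "associated_with", "UMLS:C0015672", "disease",
           "Fatigue", ref = "DisGeNET#1"),
    toyRow("ENTREZ:3569", "associated_with", "UMLS:C0015672", "disease",
           "Fatigue", ref = "OpenTargets#1"))
  g <- buildGraph(tab, rows, meta)
  expect_equal(nrow(graphNodes(g)), 3L)
  expect_equal(nrow(graphEdges(g)), 2L)
  expect_true(all(vapply(graphEdges(g)$provenance, nrow, integer(1)) == 1L))

  # the SAME triple from two sources -> 1 edge, 2 provenance entries
  rows2 <- rbind(
    toyRow("ENTREZ:7157", "associated_with", "UMLS:C0015672", "disease",
           "Fatigue", ref = "DisGeNET#1"),
    toyRow("ENTREZ:7157", "associated_with", "UMLS:C0015672", "disease",
           "Fatigue", ref = "OpenTargets#1"))
  g2 <- buildGraph(tab, rows2, meta)
  expect_equal(nrow(graphEdges(g2)), 1L)
  expect_equal(nrow(graphEdges(g2)$provenance[[1]]), 2L)
  expect_setequal(graphEdges(g2)$provenance[[1]]$source_name,
                  c("DisGeNET", "OpenTargets"))
})

test_that("DEA statistics land on gene nodes and building is deterministic", {
  tab <- toyHarmonized(dea = TRUE)
  g1 <- buildGraph(tab)
  a <- graphNodes(g1)$attributes[[
    which(graphNodes(g1)$key == "ENTREZ:7157")]]
  expect_equal(a$effect_size, 1.5)
  expect_equal(a$significance, 0.01)
  g2 <- buildGraph(tab)
  expect_same_graph(g1, g2)
})

test_that("unknown subjects and node-type conflicts are integrity errors", {
  tab <- toyHarmonized()
  meta <- toyMetadata("DisGeNET#1", "DisGeNET")
  ghost <- toyRow("ENTREZ:404", "associated_with", "UMLS:C1", "disease",
                  "x", ref = "DisGeNET#1")
  expect_error(buildGraph(tab, ghost, meta), class = "ckg_integrity_error")

  conflict <- rbind(
    toyRow("ENTREZ:7157", "associated_with", "X:1", "disease", "as disease",
           ref = "DisGeNET#1"),
    toyRow("ENTREZ:7157", "part_of", "X:1", "pathway", "as pathway",
           ref = "DisGeNET#1"))
  expect_error(buildGraph(tab, conflict, meta),
               class = "ckg_conflict_error")
})

test_that("merge order does not matter: sources A then B equal B then A", {
  tab <- demoTable(4)
  for (seed in c(2, 5, 9)) {
    out <- annotateTable(tab, c("DisGeNET", "OpenTargets", "STRING"),
                         fixtureFetcher(seed, 0.6))
    ord <- order(out$rows$metadata_ref)
    fwd <- buildGraph(tab, out$rows[ord, ], out$metadata)
    rev <- suppressWarnings(
      buildGraph(tab, out$rows[base::rev(ord), ], out$metadata))
    expect_equal(graphNodes(fwd)$key, graphNodes(rev)$key)
    expect_equal(graphEdges(fwd)[c("subject_key", "relation", "object_key")],
                 graphEdges(rev)[c("subject_key", "relation", "object_key")])
    expect_identical(graphEdges(fwd)$provenance, graphEdges(rev)$provenance)
  }
})

test_that("annotate+build twice from identical fixtures is idempotent", {
  tab <- demoTable(3)
  run <- function() {
    out <- annotateTable(tab, c("DisGeNET", "MINERVA"),
                         fixtureFetcher(13, 0.8))
    buildGraph(tab, out$rows, out$metadata)
  }
  expect_same_graph(run(), run())
})

test_that("node and edge counts obey the conservation law", {
  tab <- demoTable(5)
  out <- annotateTable(tab, c("DisGeNET", "OpenTargets", "MINERVA",
                              "STRING"), fixtureFetcher(21, 0.5))
  g <- buildGraph(tab, out$rows, out$metadata)
  table_keys <- harmonizedRows(tab)$canonical_key
  other_keys <- setdiff(unique(c(out$rows$subject_key,
                                 out$rows$object_key)), table_keys)
  expect_equal(nrow(graphNodes(g)),
               length(table_keys) + length(other_keys))
  triples <- unique(paste(out$rows$subject_key, out$rows$relation,
                          out$rows$object_key))
  expect_equal(nrow(graphEdges(g)), length(triples))
})

test_that("context nodes insert, link, and merge idempotently", {
  g <- toyGraph()
  genes <- graphNodes(g)$key[graphNodes(g)$node_type == "gene"]
  disease <- graphNodes(g)$key[graphNodes(g)$node_type == "disease"]
  links <- data.frame(entity_key = c(genes, disease),
                      relation = "associated_with",
                      stringsAsFactors = FALSE)
  g2 <- addContextNode(g, "UMLS:C5433293", "disease", "Long COVID-19",
                       links = links, provenance_tag = "literature")
  expect_equal(nrow(graphNodes(g2)), nrow(graphNodes(g)) + 1L)
  expect_equal(nrow(graphEdges(g2)), nrow(graphEdges(g)) + 3L)
  expect_equal(nrow(validateGraph(g2)), 0L)

  # node-only insertion
  g3 <- addContextNode(g, "UMLS:C0000001", "disease", "other")
  expect_equal(nrow(graphEdges(g3)), nrow(graphEdges(g)))

  # repeated insertion merges instead of duplicating
  g4 <- addContextNode(g2, "UMLS:C5433293", "disease", "Long COVID-19",
                       links = links, provenance_tag = "literature")
  expect_equal(nrow(graphNodes(g4)), nrow(graphNodes(g2)))
  expect_equal(nrow(graphEdges(g4)), nrow(graphEdges(g2)))

  expect_error(addContextNode(g, "UMLS:C2", "disease", "x",
                              links = data.frame(entity_key = "NOPE:1",
                                                 relation = "associated_with")),
               regexp = "NOPE:1", class = "ckg_integrity_error")
})

test_that("validateGraph reports broken invariants precisely", {
  g <- toyGraph()
  expect_equal(nrow(validateGraph(g)), 0L)

  broken <- g
  broken@edges$provenance[[1]] <- ContextKG:::emptyProvenance()
  rep <- validateGraph(broken)
  expect_equal(rep$rule, "empty_provenance")

  dangling <- g
  dangling@edges$object_key[1] <- "GHOST:1"
  rep2 <- validateGraph(dangling)
  expect_equal(rep2$rule, "dangling_endpoint")
  expect_equal(rep2$detail, "GHOST:1")

  loop <- g
  loop@edges$object_key[1] <- loop@edges$subject_key[1]
  rep3 <- validateGraph(loop)
  expect_true("self_loop" %in% rep3$rule)
})

test_that("random fixture graphs stay inside the closed vocabularies", {
  for (seed in 1:10) {
    g <- randomPropertyGraph(seed, n_nodes = 15, n_edges = 25)
    expect_equal(nrow(validateGraph(g)), 0L)
    expect_true(all(graphNodes(g)$node_type %in% nodeTypeVocabulary()))
    expect_true(all(graphEdges(g)$relation %in% relationVocabulary()))
  }
})
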