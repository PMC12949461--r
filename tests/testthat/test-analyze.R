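test_that("summaries count nodes, edges, and per-source contributions", {
  tab <- mapIdentifiers(parseInput(character(), "gene_list"),
                        ContextKG:::emptyMappings())
  s0 <- summarizeGraph(buildGraph(tab))
  expect_equal(s0@node_count_total, 0L)
  expect_equal(s0@edge_count_total, 0L)
  expect_length(s0@nodes_by_type, 0L)

  # toy graph with one 2-source edge: edges_by_source sums to 3
  tabg <- toyHarmonized()
  meta <- toyMetadata(c("DisGeNET#1", "OpenTargets#1"),
                      c("DisGeNET", "OpenTargets"))
  rows <- rbind(
    toyRow("ENTREZ:7157", "associated_with", "UMLS:C0015672", "disease",
           "Fatigue", ref = "DisGeNET#1"),
    toyRow("ENTREZ:7157", "associated_with", "UMLS:C0015672", "disease",
           "Fatigue", ref = "OpenTargets#1"),
    toyRow("ENTREZ:3569", "associated_with", "UMLS:C0015672", "disease",
           "Fatigue", ref = "DisGeNET#1"))
  g <- buildGraph(tabg, rows, meta)
  s <- summarizeGraph(g)
  expect_equal(s@edge_count_total, 2L)
  expect_equal(sum(s@edges_by_source), 3L)
  expect_equal(s@unannotated_input_entities, 0L)
})

test_that("summary invariant sums hold on arbitrary fixture graphs", {
  for (seed in c(3, 17, 25)) {
    tab <- demoTable(4)
    out <- annotateTable(tab, c("DisGeNET", "STRING", "MINERVA"),
                         fixtureFetcher(seed, 0.5))
    g <- buildGraph(tab, out$rows, out$metadata)
    s <- summarizeGraph(g)
    expect_equal(sum(s@nodes_by_type), s@node_count_total)
    expect_equal(sum(s@edges_by_relation), s@edge_count_total)
    expect_gte(sum(s@edges_by_source), s@edge_count_total)
  }
})

test_that("unannotated input entities are counted", {
  tab <- demoTable(3)
  g <- buildGraph(tab)  # no annotation at all
  s <- summarizeGraph(g)
  expect_equal(s@unannotated_input_entities, 3L)
})

test_that("summary files are written in JSON and TSV", {
  s <- summarizeGraph(toyGraph())
  fj <- withr::local_tempfile(fileext = ".json")
  writeSummary(s, fj)
  parsed <- jsonlite::fromJSON(fj)
  expect_equal(parsed$node_count_total, 3L)
  ft <- withr::local_tempfile(fileext = ".tsv")
  writeSummary(s, ft)
  expect_true("node_count_total" %in% read.delim(ft)$measure)
})

# a 6-node path gene graph: g1 -iw- g2 -iw- g3 ... -iw- g6
pathGraph <- function() {
  syms <- paste0("G", 1:6)
  maps <- data.frame(source_namespace = "HGNC", source_id = syms,
                     target_namespace = "ENTREZ",
                     target_id = as.character(1:6),
                     stringsAsFactors = FALSE)
  tab <- mapIdentifiers(parseInput(syms, "gene_list"), maps)
  rows <- do.call(rbind, lapply(1:5, function(i)
    toyRow(paste0("ENTREZ:", i), "interacts_with",
           paste0("ENTREZ:", i + 1), "gene", paste0("G", i + 1),
           ref = "STRING#1")))
  buildGraph(tab, rows, toyMetadata("STRING#1", "STRING"))
}

test_that("subgraph extraction matches the brute-force BFS oracle", {
  g <- pathGraph()
  s0 <- extractSubgraph(g, "ENTREZ:1", 0)
  expect_equal(graphNodes(s0)$key, "ENTREZ:1")
  expect_equal(nrow(graphEdges(s0)), 0L)

  s2 <- extractSubgraph(g, "ENTREZ:1", 2)
  expect_equal(sort(graphNodes(s2)$key),
               c("ENTREZ:1", "ENTREZ:2", "ENTREZ:3"))
  expect_equal(nrow(graphEdges(s2)), 2L)

  expect_error(extractSubgraph(g, "ENTREZ:404", 1),
               regexp = "ENTREZ:404", class = "ckg_lookup_error")
})

test_that("subgraph node sets agree with the oracle and grow with hops", {
  for (seed in c(7, 19, 28)) {
    g <- randomPropertyGraph(seed, n_nodes = 50, n_edges = 90)
    anchor <- graphNodes(g)$key[1 + ContextKG:::strHash(seed, "a") %%
                                  nrow(graphNodes(g))]
    prev <- character()
    for (h in 0:4) {
      sub <- extractSubgraph(g, anchor, h)
      expect_equal(sort(graphNodes(sub)$key),
                   bruteForceNeighborhood(g, anchor, h))
      expect_true(all(prev %in% graphNodes(sub)$key))
      expect_equal(nrow(validateGraph(sub)), 0L)
      prev <- graphNodes(sub)$key
    }
  }
})

test_that("type and relation filters post-filter the neighborhood", {
  g <- toyGraph()
  onlygenes <- extractSubgraph(g, "ENTREZ:7157", 2,
                               node_type_filter = "gene")
  expect_true(all(graphNodes(onlygenes)$node_type == "gene"))
  expect_equal(nrow(graphEdges(onlygenes)), 0L)

  none <- extractSubgraph(g, "ENTREZ:7157", 2,
                          relation_filter = character())
  expect_gt(nrow(graphNodes(none)), 0L)
  expect_equal(nrow(graphEdges(none)), 0L)
})

test_that("training triples: positives for every edge, ratio 0, determinism", {
  g <- toyGraph()
  t0 <- exportTrainingTriples(g, 0, seed = 5)
  expect_equal(nrow(t0), nrow(graphEdges(g)))
  expect_true(all(t0$label == 1L))

  g2 <- randomPropertyGraph(8, n_nodes = 15, n_edges = 25)
  a <- exportTrainingTriples(g2, 1, seed = 123)
  b <- exportTrainingTriples(g2, 1, seed = 123)
  expect_identical(a, b)
  expect_equal(sum(a$label == 0L), nrow(graphEdges(g2)))
})

test_that("when the request exhausts the free combinations, sampling is exhaustive", {
  # two genes, one disease; incidence gene-associated_with-disease only.
  # Edges: g1->d. Free combinations: g2->d ... enumerate by hand.
  tab <- toyHarmonized()
  rows <- toyRow("ENTREZ:7157", "associated_with", "UMLS:C0015672",
                 "disease", "Fatigue", ref = "DisGeNET#1")
  g <- buildGraph(tab, rows, toyMetadata("DisGeNET#1", "DisGeNET"))
  inc <- data.frame(subject_type = "gene", relation = "associated_with",
                    object_type = "disease", stringsAsFactors = FALSE)
  tt <- exportTrainingTriples(g, 1, seed = 3, incidence = inc)
  neg <- tt[tt$label == 0L, ]
  expect_equal(nrow(neg), 1L)
  expect_equal(neg$head, "ENTREZ:3569")
  expect_equal(neg$tail, "UMLS:C0015672")

  expect_error(exportTrainingTriples(g, 5, seed = 3, incidence = inc),
               class = "ckg_infeasible_error")
})

test_that("positives and negatives are disjoint for any seed", {
  g <- randomPropertyGraph(14, n_nodes = 18, n_edges = 30)
  for (seed in 1:20) {
    tt <- exportTrainingTriples(g, 0.5, seed = seed)
    keys <- paste(tt$head, tt$relation, tt$tail)
    expect_length(intersect(keys[tt$label == 1L], keys[tt$label == 0L]),
                  0L)
    expect_false(anyDuplicated(keys[tt$label == 0L]) > 0)
  }
})

test_that("summary plots are written as non-empty files", {
  dir <- withr::local_tempdir()
  s <- summarizeGraph(toyGraph())
  paths <- plotSummary(s, file.path(dir, "plots"))
  expect_length(paths, 3L)
  expect_true(all(file.exists(paths)))
  expect_true(all(file.size(paths) > 0))

  tab <- mapIdentifiers(parseInput(character(), "gene_list"),
                        ContextKG:::emptyMappings())
  s0 <- summarizeGraph(buildGraph(tab))
  p0 <- plotSummary(s0, file.path(dir, "empty"))
  expect_true(all(file.size(p0) > 0))

  expect_error(suppressWarnings(plotSummary(s, "/proc/zzz/plots")),
               class = "ckg_io_error")
})

test_that("training triples TSV round-trips", {
  g <- toyGraph()
  f <- withr::local_tempfile(fileext = ".tsv")
  writeTrainingTriples(exportTrainingTriples(g, 0, 1), f)
  back <- read.delim(f)
  expect_equal(nrow(back), nrow(graphEdges(g)))
  expect_equal(names(back), c("head", "relation", "tail", "label"))
})
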