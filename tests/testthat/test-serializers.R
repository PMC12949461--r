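test_that("exactly three export formats are exposed", {
  expect_equal(sort(exportFormats()), c("cytoscape", "graphml", "rdf"))
})

test_that("Cytoscape JSON has one element per node and edge, stable bytes", {
  tab <- mapIdentifiers(parseInput(character(), "gene_list"),
                        ContextKG:::emptyMappings())
  empty <- buildGraph(tab)
  doc <- jsonlite::fromJSON(toCytoscapeJson(empty), simplifyVector = FALSE)
  expect_length(doc$elements$nodes, 0L)
  expect_length(doc$elements$edges, 0L)

  g <- toyGraph()  # 3 nodes, 2 edges
  doc <- jsonlite::fromJSON(toCytoscapeJson(g), simplifyVector = FALSE)
  expect_length(doc$elements$nodes, 3L)
  expect_length(doc$elements$edges, 2L)
  e1 <- doc$elements$edges[[1]]$data
  expect_true(all(c("source", "target", "relation", "provenance") %in%
                    names(e1)))
  expect_match(e1$provenance, "@fixture-1@2026-01-15")

  expect_identical(toCytoscapeJson(g), toCytoscapeJson(g))
})

test_that("GraphML round-trips graphs exactly", {
  tab <- mapIdentifiers(parseInput(character(), "gene_list"),
                        ContextKG:::emptyMappings())
  empty <- buildGraph(tab)
  expect_same_graph(fromGraphml(toGraphml(empty)), empty)

  big <- randomPropertyGraph(99, n_nodes = 50, n_edges = 80)
  expect_same_graph(fromGraphml(toGraphml(big)), big)
})

test_that("GraphML import rejects undeclared attribute keys", {
  g <- toyGraph()
  xml <- toGraphml(g)
  bad <- sub('key="ns_label"', 'key="ns_mystery"', xml)
  expect_error(fromGraphml(bad), regexp = "ns_mystery",
               class = "ckg_format_error")
})

test_that("RDF export matches the hand-enumerated template counts", {
  # empty graph: only the 4 dataset-header triples
  tab <- mapIdentifiers(parseInput(character(), "gene_list"),
                        ContextKG:::emptyMappings())
  empty <- buildGraph(tab)
  expect_equal(nrow(toRdf(empty)), 4L)

  # 1 gene + 1 disease + 1 associated_with edge, 1 provenance entry,
  # no xrefs/attributes:
  #   header 4
  # + 2 nodes x (type + label) = 4
  # + association node: type + 2 has_part = 3
  # + provenance record: link + label/version/date = 4
  # total 15
  tab1 <- mapIdentifiers(parseInput("ENTREZ:7157", "gene_list"),
                         ContextKG:::emptyMappings())
  rows <- toyRow("ENTREZ:7157", "associated_with", "UMLS:C0015672",
                 "disease", "Fatigue", ref = "DisGeNET#1")
  g1 <- buildGraph(tab1, rows, toyMetadata("DisGeNET#1", "DisGeNET"))
  tr <- toRdf(g1)
  expect_equal(nrow(tr), 15L)

  # a direct (non-reified) relation: 1 predicate triple + 7-per-entry
  # reification block
  rows2 <- toyRow("ENTREZ:7157", "part_of", "WIKIPATHWAYS:WP1",
                  "pathway", "P", ref = "DisGeNET#1")
  g2 <- buildGraph(tab1, rows2, toyMetadata("DisGeNET#1", "DisGeNET"))
  expect_equal(nrow(toRdf(g2)), 4L + 4L + 1L + 7L)

  expect_identical(attr(toRdf(g1), "turtle"), attr(toRdf(g1), "turtle"))
})

test_that("the triple count law holds against the brute-force enumerator", {
  for (seed in 1:12) {
    g <- randomPropertyGraph(seed, n_nodes = sample(3:20, 1),
                             n_edges = sample(3:30, 1))
    expect_equal(nrow(toRdf(g)), bruteForceTripleCount(g),
                 label = paste("seed", seed))
  }
})

test_that("every Turtle line is a well-formed triple", {
  g <- randomPropertyGraph(4, n_nodes = 10, n_edges = 15)
  ttl <- attr(toRdf(g), "turtle")
  lines <- strsplit(ttl, "\n")[[1]]
  lines <- lines[nzchar(lines)]
  pat <- paste0("^<[^>]+> <[^>]+> ",
                "(<[^>]+>|\"([^\"\\\\]|\\\\.)*\"(\\^\\^<[^>]+>)?)",
                " \\.$")
  expect_true(all(grepl(pat, lines)))
})

test_that("literals with quotes and newlines are escaped", {
  g <- toyGraph()
  g@nodes$label[1] <- "say \"hi\"\nline2"
  ttl <- attr(toRdf(g), "turtle")
  expect_true(grepl('say \\\\"hi\\\\"\\\\nline2', ttl))
})

test_that("SHACL shapes cover instantiated classes only and data conforms", {
  g <- toyGraph()  # gene + disease only
  shapes <- generateShacl(g)
  sh_iri <- "http://www.w3.org/ns/shacl#NodeShape"
  n_shapes <- sum(shapes$object == sh_iri)
  expect_equal(n_shapes, 2L)

  tab <- mapIdentifiers(parseInput(character(), "gene_list"),
                        ContextKG:::emptyMappings())
  empty <- buildGraph(tab)
  expect_equal(sum(generateShacl(empty)$object == sh_iri), 0L)

  v <- validateShacl(toRdf(g), shapes)
  expect_true(v$conforms)

  # shapes do detect missing labels
  mutilated <- toRdf(g)
  mutilated <- mutilated[
    mutilated$predicate != "http://www.w3.org/2000/01/rdf-schema#label", ]
  v2 <- validateShacl(mutilated, shapes)
  expect_false(v2$conforms)
  expect_gt(nrow(v2$violations), 0L)
})

test_that("SHACL self-conformance holds across random fixture graphs", {
  for (seed in 31:40) {
    g <- randomPropertyGraph(seed, n_nodes = 12, n_edges = 20)
    v <- validateShacl(toRdf(g), generateShacl(g))
    expect_true(v$conforms, label = paste("seed", seed))
  }
})

test_that("the triplestore manager records deterministic requests", {
  echo <- function(req) req
  ts <- triplestoreManager(list(name = "graphdb-local",
                                url = "http://localhost:7200"), echo)
  ts$create_repository("pcs")
  expect_equal(ts$requests()[[1]]$path, "/rest/repositories/pcs")
  expect_match(ts$requests()[[1]]$body, '"id": "pcs"')

  expect_error(ts$upload(""), class = "ckg_empty_payload_error")

  q <- "SELECT * WHERE { ?s ?p ?o } LIMIT 5"
  out <- ts$sparql_query(q)
  expect_identical(out$body, q)

  ttl <- attr(toRdf(toyGraph()), "turtle")
  up <- ts$upload(ttl)
  expect_identical(up$body, ttl)

  boom <- triplestoreManager(list(name = "down"),
                             function(req) stop("refused"))
  expect_error(boom$sparql_query("SELECT"), regexp = "down",
               class = "ckg_transport_error")
})
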