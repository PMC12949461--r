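test_that("parseInput handles the three input kinds", {
  expect_equal(nrow(parseInput(character(), "gene_list")), 0L)

  recs <- parseInput(c("TP53", "IL6", "CXCL10"), "gene_list")
  expect_equal(nrow(recs), 3L)
  expect_true(all(recs$entity_kind == "gene"))
  expect_true(all(is.na(recs$effect_size)))

  dea <- data.frame(identifier = paste0("G", 1:5),
                    log2fc = c(-1.2, 0.5, 2.1, -0.3, 1.8),
                    p_value = c(0.01, 0.2, 0.001, 0.5, 0.04))
  recs <- parseInput(dea, "dea_table")
  expect_equal(nrow(recs), 5L)
  expect_equal(recs$effect_size, dea$log2fc)
  expect_equal(recs$significance, dea$p_value)

  mets <- parseInput(c("PUBCHEM:1983", "glucose"), "metabolite_list")
  expect_equal(mets$entity_kind, c("metabolite", "metabolite"))
  expect_equal(mets$declared_namespace, c("PUBCHEM", NA))
})

test_that("parseInput preserves order, keeps duplicates, drops blanks", {
  recs <- parseInput(c("B", "", "A", "  ", "B"), "gene_list")
  expect_equal(recs$raw_identifier, c("B", "A", "B"))
})

test_that("parseInput rejects bad kinds, schemas and values", {
  expect_error(parseInput("x", "protein_list"), class = "ckg_unsupported_kind_error")
  expect_error(parseInput(data.frame(gene = "A"), "dea_table"),
               regexp = "identifier", class = "ckg_schema_error")
  bad <- data.frame(identifier = c("A", "B"), log2fc = c("1.1", "oops"),
                    p_value = c(0.1, 0.2))
  expect_error(parseInput(bad, "dea_table"), regexp = "row 2",
               class = "ckg_parse_error")
  oob <- data.frame(identifier = "A", log2fc = 1, p_value = 1.7)
  expect_error(parseInput(oob, "dea_table"), class = "ckg_parse_error")
})

test_that("DEA column names are configurable", {
  dea <- data.frame(gene = c("A", "B"), lfc = c(1, -1), padj = c(0.1, 0.2))
  recs <- parseInput(dea, "dea_table",
                     column_map = list(identifier = "gene", effect = "lfc",
                                       significance = "padj"))
  expect_equal(recs$raw_identifier, c("A", "B"))
  expect_equal(recs$effect_size, c(1, -1))
})

test_that("mapIdentifiers trivial cases: no mappings, identity", {
  recs <- parseInput(c("TP53", "IL6"), "gene_list")
  tab <- mapIdentifiers(recs, ContextKG:::emptyMappings())
  expect_equal(nrow(harmonizedRows(tab)), 0L)
  expect_equal(nrow(unmappedRecords(tab)), 2L)

  recs2 <- parseInput(c("ENTREZ:7157", "ENTREZ:3569"), "gene_list")
  tab2 <- mapIdentifiers(recs2, ContextKG:::emptyMappings())
  expect_equal(harmonizedRows(tab2)$canonical_key,
               c("ENTREZ:7157", "ENTREZ:3569"))
  expect_equal(nrow(unmappedRecords(tab2)), 0L)
})

test_that("mapIdentifiers maps covered records and reports the rest", {
  maps <- data.frame(
    source_namespace = "HGNC",
    source_id = c("A1", "A2", "A3", "A4"),
    target_namespace = "ENTREZ", target_id = c("11", "12", "13", "14"),
    stringsAsFactors = FALSE)
  recs <- parseInput(c("A1", "A2", "A3", "A4", "A5"), "gene_list")
  tab <- mapIdentifiers(recs, maps)
  expect_equal(nrow(harmonizedRows(tab)), 4L)
  expect_equal(unmappedRecords(tab)$raw_identifier, "A5")
  # brute-force lookup agrees row by row
  for (i in 1:5) {
    exp_key <- bruteForceResolve(NA, paste0("A", i), "ENTREZ", maps, "HGNC")
    got <- harmonizedRows(tab)$canonical_key[
      harmonizedRows(tab)$raw_identifier == paste0("A", i)]
    if (is.na(exp_key)) expect_length(got, 0L) else expect_equal(got, exp_key)
  }
})

test_that("one-to-many mappings pick the lexicographic minimum and keep xrefs", {
  maps <- data.frame(source_namespace = "HGNC", source_id = "DUP",
                     target_namespace = "ENTREZ",
                     target_id = c("900", "100"), stringsAsFactors = FALSE)
  tab <- mapIdentifiers(parseInput("DUP", "gene_list"), maps)
  hr <- harmonizedRows(tab)
  expect_equal(hr$canonical_key, "ENTREZ:100")
  xr <- hr$xrefs[[1]]
  expect_setequal(unname(xr[names(xr) == "ENTREZ"]), c("100", "900"))
})

test_that("pivot hop through the hub namespace is followed, depth two is not", {
  maps <- data.frame(
    source_namespace = c("SYM", "HGNC", "ENSEMBL"),
    source_id = c("foo", "FOO", "ENSG1"),
    target_namespace = c("HGNC", "ENTREZ", "HGNC"),
    target_id = c("FOO", "77", "FOO"), stringsAsFactors = FALSE)
  recs <- parseInput("SYM:foo", "gene_list")
  tab <- mapIdentifiers(recs, maps, hub_namespace = "HGNC")
  expect_equal(harmonizedRows(tab)$canonical_key, "ENTREZ:77")

  # needs two hops (ENSEMBL -> HGNC -> ... -> ENTREZ via another pivot):
  # a chain source->X->hub->target must NOT resolve
  deep <- data.frame(
    source_namespace = c("SYM", "MID", "HGNC"),
    source_id = c("bar", "m1", "H1"),
    target_namespace = c("MID", "HGNC", "ENTREZ"),
    target_id = c("m1", "H1", "88"), stringsAsFactors = FALSE)
  tab2 <- mapIdentifiers(parseInput("SYM:bar", "gene_list"), deep,
                         hub_namespace = "HGNC")
  expect_equal(nrow(harmonizedRows(tab2)), 0L)
})

test_that("duplicates merge silently when stats agree and raise otherwise", {
  maps <- data.frame(source_namespace = "HGNC", source_id = c("A", "B"),
                     target_namespace = "ENTREZ", target_id = c("1", "1"),
                     stringsAsFactors = FALSE)
  dea <- data.frame(identifier = c("A", "B"), log2fc = c(1.5, 1.5),
                    p_value = c(0.01, 0.01))
  tab <- mapIdentifiers(parseInput(dea, "dea_table"), maps)
  expect_equal(nrow(harmonizedRows(tab)), 1L)

  dea2 <- data.frame(identifier = c("A", "B"), log2fc = c(1.5, -2),
                     p_value = c(0.01, 0.01))
  expect_error(mapIdentifiers(parseInput(dea2, "dea_table"), maps),
               regexp = "A, B|A', 'B|A.*B",
               class = "ckg_merge_conflict_error")
})

test_that("missing namespace policy for a present kind is a configuration error", {
  recs <- parseInput("glucose", "metabolite_list")
  expect_error(mapIdentifiers(recs, target_namespace_policy = c(gene = "ENTREZ")),
               class = "ckg_config_error")
})

test_that("partition, idempotence and oracle equivalence hold over random cases", {
  nss <- c("HGNC", "SYM", "ENSEMBL")
  for (seed in 1:8) {
    set.seed(seed)
    n_ids <- sample(5:40, 1)
    ids <- paste0(sample(nss, n_ids, replace = TRUE), ":",
                  "g", sample(1:30, n_ids, replace = TRUE))
    n_map <- sample(10:200, 1)
    maps <- data.frame(
      source_namespace = sample(nss, n_map, replace = TRUE),
      source_id = paste0("g", sample(1:30, n_map, replace = TRUE)),
      target_namespace = sample(c("ENTREZ", "HGNC", "ENSEMBL"), n_map,
                                replace = TRUE),
      target_id = paste0("t", sample(1:40, n_map, replace = TRUE)),
      stringsAsFactors = FALSE)
    recs <- parseInput(ids, "gene_list")
    tab <- mapIdentifiers(recs, maps)

    # partition: every distinct input in exactly one of rows/unmapped
    mapped_raw <- harmonizedRows(tab)$raw_identifier
    all_mapped_raw <- unlist(lapply(seq_len(nrow(harmonizedRows(tab))),
      function(i) harmonizedRows(tab)$raw_identifier[i]))
    un_raw <- unmappedRecords(tab)$raw_identifier
    expect_length(intersect(all_mapped_raw, un_raw), 0L)
    # each distinct raw id is accounted for
    covered <- unique(c(un_raw, all_mapped_raw))
    merged_away <- setdiff(unique(ids), covered)
    # ids merged into an existing canonical row are still mapped: their
    # canonical key must exist
    for (m in merged_away) {
      cur <- ContextKG:::splitCurie(m)
      key <- bruteForceResolve(cur$namespace, cur$accession, "ENTREZ",
                               maps, "HGNC")
      expect_false(is.na(key))
      expect_true(key %in% harmonizedRows(tab)$canonical_key)
    }

    # oracle equivalence on canonical keys
    exp_keys <- unique(stats::na.omit(vapply(unique(ids), function(m) {
      cur <- ContextKG:::splitCurie(m)
      bruteForceResolve(cur$namespace, cur$accession, "ENTREZ", maps,
                        "HGNC")
    }, character(1))))
    expect_setequal(harmonizedRows(tab)$canonical_key, exp_keys)

    # idempotence: canonical keys fed back map to themselves
    if (nrow(harmonizedRows(tab))) {
      back <- mapIdentifiers(parseInput(harmonizedRows(tab)$canonical_key,
                                        "gene_list"), maps)
      expect_setequal(harmonizedRows(back)$canonical_key,
                      harmonizedRows(tab)$canonical_key)
    }
  }
})

test_that("loadMappingTable parses fixtures, records checksums, rejects bad rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("source_namespace\tsource_id\ttarget_namespace\ttarget_id", f)
  m <- loadMappingTable(f)
  expect_equal(nrow(m), 0L)

  demoMappingTable(f)
  m <- loadMappingTable(f)
  expect_equal(nrow(m), 40L)
  expect_match(attr(m, "provenance"), "md5:[0-9a-f]{32}")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source_namespace\tsource_id\ttarget_namespace\ttarget_id",
               "HGNC\tTP53\tENTREZ\t7157",
               "HGNC\tIL6\tENTREZ"), bad)
  expect_error(loadMappingTable(bad), regexp = "line 3",
               class = "ckg_parse_error")

  expect_error(loadMappingTable(list(name = "svc")),
               class = "ckg_config_error")
  got <- loadMappingTable(list(name = "svc"), fetcher = function(s)
    "source_namespace\tsource_id\ttarget_namespace\ttarget_id\nHGNC\tA\tENTREZ\t1")
  expect_equal(got$target_id, "1")
  expect_match(attr(got, "provenance"), "service:svc")
})

test_that("unmapped report is written as TSV with reasons", {
  tab <- mapIdentifiers(parseInput(c("NOPE1", "NOPE2"), "gene_list"),
                        ContextKG:::emptyMappings())
  f <- withr::local_tempfile(fileext = ".tsv")
  writeUnmappedReport(tab, f)
  rep <- read.delim(f)
  expect_equal(rep$raw_identifier, c("NOPE1", "NOPE2"))
  expect_true(all(grepl("no mapping chain", rep$reason)))
})
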