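# shared fixtures and independent oracles for the test suite

test_path_fixture <- function(src, file) {
  system.file("extdata", "fixtures", src, file, package = "ContextKG")
}

# first n demo genes, harmonized through the demo mapping table
demoTable <- function(n = 3) {
  g <- ContextKG:::demoGenes()[seq_len(n), ]
  recs <- parseInput(g$symbol, "gene_list")
  mapIdentifiers(recs, demoMappingTable())
}

toyHarmonized <- function(symbols = c("TP53", "IL6"),
                          entrez = c("7157", "3569"),
                          dea = FALSE) {
  maps <- data.frame(source_namespace = "HGNC", source_id = symbols,
                     target_namespace = "ENTREZ", target_id = entrez,
                     stringsAsFactors = FALSE)
  recs <- parseInput(symbols, "gene_list")
  if (dea) {
    recs$effect_size <- seq_along(symbols) + 0.5
    recs$significance <- 0.01 * seq_along(symbols)
  }
  mapIdentifiers(recs, maps)
}

toyMetadata <- function(refs, sources) {
  data.frame(metadata_ref = refs, source_name = sources,
             source_version = "fixture-1", retrieval_date = "2026-01-15",
             input_count = 1L, result_count = 1L, duration_seconds = 0,
             stringsAsFactors = FALSE)
}

toyRow <- function(subject, relation, object, object_type, label = object,
                   ref = NA_character_) {
  ContextKG:::makeAnnotationRow(subject, relation, object, object_type,
                                label, metadata_ref = ref)
}

# a small valid graph: 2 genes, 1 disease, 2 edges
toyGraph <- function() {
  tab <- toyHarmonized()
  rows <- rbind(
    toyRow("ENTREZ:7157", "associated_with", "UMLS:C0015672", "disease",
           "Fatigue", ref = "DisGeNET#1"),
    toyRow("ENTREZ:3569", "associated_with", "UMLS:C0015672", "disease",
           "Fatigue", ref = "OpenTargets#1"))
  meta <- toyMetadata(c("DisGeNET#1", "OpenTargets#1"),
                      c("DisGeNET", "OpenTargets"))
  buildGraph(tab, rows, meta)
}

# structural dialect checks (stand-ins for full grammars): balanced
# braces/brackets, mandatory clause keywords, sane URL shape
structurallyValidGraphql <- function(x) {
  chars <- strsplit(x, "")[[1]]
  depth <- 0
  for (ch in chars) {
    if (ch == "{") depth <- depth + 1
    if (ch == "}") depth <- depth - 1
    if (depth < 0) return(FALSE)
  }
  depth == 0 && grepl("^\\s*query\\s+\\w+\\s*\\{", x)
}

structurallyValidSparql <- function(x) {
  chars <- strsplit(x, "")[[1]]
  depth <- 0
  for (ch in chars) {
    if (ch == "{") depth <- depth + 1
    if (ch == "}") depth <- depth - 1
    if (depth < 0) return(FALSE)
  }
  depth == 0 && grepl("SELECT\\s+.+\\s+WHERE\\s*\\{", x)
}

structurallyValidUrl <- function(x) {
  grepl("^https?://[^/]+/\\S*$", x) && !grepl("\\s", x)
}

# independent BFS oracle: undirected hop expansion by repeated scans
bruteForceNeighborhood <- function(graph, anchors, hops) {
  ed <- graphEdges(graph)
  reached <- unique(anchors)
  for (h in seq_len(hops)) {
    add <- character()
    for (i in seq_len(nrow(ed))) {
      if (ed$subject_key[i] %in% reached) add <- c(add, ed$object_key[i])
      if (ed$object_key[i] %in% reached) add <- c(add, ed$subject_key[i])
    }
    new_reached <- unique(c(reached, add))
    if (length(new_reached) == length(reached)) break
    reached <- new_reached
  }
  sort(reached)
}

# independent per-element triple enumerator mirroring the documented
# RDF template, written against the contract rather than the serializer
bruteForceTripleCount <- function(graph) {
  nd <- graphNodes(graph)
  ed <- graphEdges(graph)
  total <- 4  # dataset header
  for (i in seq_len(nrow(nd))) {
    total <- total + 2            # type + label
    total <- total + length(nd$xrefs[[i]])
    for (v in nd$attributes[[i]]) {
      if (is.numeric(v)) total <- total + 3 * length(v)
      else total <- total + length(v)
    }
  }
  for (i in seq_len(nrow(ed))) {
    np <- nrow(ed$provenance[[i]])
    if (ed$relation[i] == "associated_with") {
      total <- total + 3 + 4 * np
    } else {
      total <- total + 1 + 7 * np
    }
    for (v in ed$attributes[[i]]) {
      if (is.numeric(v)) total <- total + 3 * length(v)
      else total <- total + length(v)
    }
  }
  total
}

# exhaustive single-hop + one-pivot-hop mapping oracle
bruteForceResolve <- function(ns, acc, target, maps, hub) {
  targets <- character()
  if (!is.na(ns) && ns == target) targets <- c(targets, acc)
  for (i in seq_len(nrow(maps))) {
    if (maps$source_id[i] == acc &&
        (is.na(ns) || maps$source_namespace[i] == ns)) {
      if (maps$target_namespace[i] == target)
        targets <- c(targets, maps$target_id[i])
      if (maps$target_namespace[i] == hub) {
        for (j in seq_len(nrow(maps))) {
          if (maps$source_namespace[j] == hub &&
              maps$source_id[j] == maps$target_id[i] &&
              maps$target_namespace[j] == target)
            targets <- c(targets, maps$target_id[j])
        }
      }
    }
  }
  if (!is.na(ns) && ns == hub) {
    for (j in seq_len(nrow(maps))) {
      if (maps$source_namespace[j] == hub && maps$source_id[j] == acc &&
          maps$target_namespace[j] == target)
        targets <- c(targets, maps$target_id[j])
    }
  }
  targets <- sort(unique(targets))
  if (!length(targets)) return(NA_character_)
  paste0(target, ":", targets[1])
}

resetRows <- function(d) {
  rownames(d) <- NULL
  d
}

expect_same_graph <- function(g1, g2) {
  expect_identical(graphNodes(g1), graphNodes(g2))
  expect_identical(graphEdges(g1), graphEdges(g2))
}
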