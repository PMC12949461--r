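#' Demo differential-expression table
#'
#' A small synthetic DEA result table over interferon-response and
#' inflammatory genes of the kind reported differentially expressed in
#' post-viral syndromes. Effect sizes and p-values are deterministic
#' functions of the seed; the table is synthetic demo data, not an
#' excerpt from any study.
#'
#' @param n number of genes (<= 10).
#' @param seed integer stream key.
#' @return data.frame with columns identifier, log2fc, p_value.
#' @export
#' @examples
#' demoDeaTable()
demoDeaTable <- function(n = 10L, seed = 42L) {
  sym <- demoGenes()$symbol
  stopifnot(n >= 1L, n <= length(sym))
  sym <- sym[seq_len(n)]
  lfc <- vapply(sym, function(s)
    round(-3 + 6 * hashUnit(seed, "lfc", s), 3), numeric(1))
  p <- vapply(sym, function(s)
    round(0.0005 + 0.04 * hashUnit(seed, "p", s), 5), numeric(1))
  data.frame(identifier = sym, log2fc = unname(lfc),
             p_value = unname(p), stringsAsFactors = FALSE)
}

# ten interferon/inflammation genes with synthetic-but-plausible
# accession layouts for each namespace the adapters need
demoGenes <- function() {
  data.frame(
    symbol = c("IFI27", "IFIT3", "CXCL10", "OAS1", "ISG15",
               "MX1", "TNF", "IL6", "CCL2", "CXCL8"),
    entrez = c("3429", "3437", "3627", "4938", "9636",
               "4599", "7124", "3569", "6347", "3576"),
    ensembl = c("ENSG00000165949", "ENSG00000119917", "ENSG00000169245",
                "ENSG00000089127", "ENSG00000187608", "ENSG00000157601",
                "ENSG00000232810", "ENSG00000136244", "ENSG00000108691",
                "ENSG00000169429"),
    string = paste0("9606.ENSP0000", sprintf("%04d", c(101, 102, 103, 104,
                                                       105, 106, 107, 108,
                                                       109, 110))),
    stringsAsFactors = FALSE)
}

#' Demo identifier-mapping table
#'
#' Mappings from HGNC symbols to Entrez, Ensembl and STRING identifiers
#' for the [demoDeaTable()] genes, in the 4-column layout
#' [loadMappingTable()] reads. Accessions for Entrez/Ensembl follow the
#' real layouts; the table is synthetic demo data.
#'
#' @param path optional file path; when given, the table is written as
#'   TSV (loadable with [loadMappingTable()]) and the path returned.
#' @return data.frame of mappings, or the path when `path` is given.
#' @export
demoMappingTable <- function(path = NULL) {
  g <- demoGenes()
  m <- rbind(
    data.frame(source_namespace = "HGNC", source_id = g$symbol,
               target_namespace = "ENTREZ", target_id = g$entrez,
               stringsAsFactors = FALSE),
    data.frame(source_namespace = "HGNC", source_id = g$symbol,
               target_namespace = "ENSEMBL", target_id = g$ensembl,
               stringsAsFactors = FALSE),
    data.frame(source_namespace = "HGNC", source_id = g$symbol,
               target_namespace = "STRING", target_id = g$string,
               stringsAsFactors = FALSE),
    data.frame(source_namespace = "HGNC", source_id = g$symbol,
               target_namespace = "HGNC", target_id = g$symbol,
               stringsAsFactors = FALSE))
  if (!is.null(path)) {
    utils::write.table(m, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(path)
  }
  attr(m, "provenance") <- "demo mapping table (synthetic)"
  m
}

typeNamespace <- function(node_type) {
  switch(node_type,
         gene = "ENTREZ", disease = "UMLS", compound = "PUBCHEM",
         anatomical_entity = "UBERON", pathway = "WIKIPATHWAYS",
         molecular_function = "GO", biological_process = "GO",
         cellular_component = "GO", side_effect = "MEDDRA",
         homolog = "HOMOLOGENE", phenotype = "HP", mirna = "MIRBASE",
         transcription_factor = "ENTREZ",
         mitochondrial_pathway = "MITOCARTA", key_event = "AOPKE",
         molecular_initiating_event = "AOPMIE",
         adverse_outcome_pathway = "AOPWIKI",
         adverse_outcome = "AOPAO", "X")
}

#' Generate a random, valid property graph
#'
#' Deterministic generator for property-based tests: node types,
#' relations, attributes, cross-references and (possibly multi-entry)
#' provenance are all drawn from hash streams keyed by the seed, so the
#' same seed always yields the identical graph. Every generated graph
#' passes [validateGraph()].
#'
#' @param seed integer stream key.
#' @param n_nodes,n_edges sizes (edges are attempted; duplicates and
#'   disallowed self-loops are skipped, so the realized edge count can
#'   be slightly lower).
#' @return a PropertyGraph.
#' @export
randomPropertyGraph <- function(seed, n_nodes = 12L, n_edges = 18L) {
  types <- nodeTypeVocabulary()
  rels <- relationVocabulary()
  srcs <- c("DisGeNET", "OpenTargets", "MINERVA", "STRING", "Bgee")

  nodes <- new.env(parent = emptyenv())
  keys <- character(n_nodes)
  for (i in seq_len(n_nodes)) {
    tp <- types[1L + strHash(seed, "ntype", i) %% length(types)]
    key <- canonicalKey(typeNamespace(tp), sprintf("A%03d", i))
    keys[i] <- key
    attrs <- structure(list(), names = character())
    if (hashUnit(seed, "hasscore", i) < 0.6)
      attrs$score <- round(hashUnit(seed, "score", i), 6)
    if (hashUnit(seed, "hastag", i) < 0.4)
      attrs$tag <- paste0("tag", 1L + strHash(seed, "tag", i) %% 5L)
    if (hashUnit(seed, "hasvec", i) < 0.2)
      attrs$levels <- round(c(hashUnit(seed, "v1", i),
                              hashUnit(seed, "v2", i)), 6)
    xr <- character()
    if (hashUnit(seed, "hasxref", i) < 0.5)
      xr <- stats::setNames(sprintf("X%03d", i), "DEMO")
    nodes[[key]] <- list(key = key, node_type = tp,
                         label = sprintf("%s %d", tp, i),
                         xrefs = dedupXrefs(xr),
                         attributes = sortAttributes(attrs))
  }

  edges <- new.env(parent = emptyenv())
  for (j in seq_len(n_edges)) {
    a <- keys[1L + strHash(seed, "ea", j) %% n_nodes]
    b <- keys[1L + strHash(seed, "eb", j) %% n_nodes]
    r <- rels[1L + strHash(seed, "er", j) %% length(rels)]
    if (a == b && r != "interacts_with") next
    ek <- paste(a, r, b, sep = "\r")
    if (!is.null(edges[[ek]])) next
    n_prov <- 1L + strHash(seed, "np", j) %% 2L
    prov <- do.call(rbind, lapply(seq_len(n_prov), function(pk) {
      s <- srcs[1L + strHash(seed, "ps", j, pk) %% length(srcs)]
      data.frame(source_name = s,
                 source_version = sprintf("fixture-%d", seed),
                 retrieval_date = "2026-01-15", stringsAsFactors = FALSE)
    }))
    attrs <- structure(list(), names = character())
    if (hashUnit(seed, "escore", j) < 0.5)
      attrs$score <- round(hashUnit(seed, "escoreval", j), 6)
    edges[[ek]] <- list(subject_key = a, relation = r, object_key = b,
                        provenance = prov, attributes = attrs)
  }
  g <- assemblePropertyGraph(nodes, edges,
                             metadata = list(query_metadata = NULL,
                                             harmonization = "random fixture",
                                             input_keys = character()))
  g
}
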