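#' Summarize a property graph
#'
#' Node and edge totals, per-type and per-relation breakdowns, per-source
#' edge counts (a multi-provenance edge counts once per distinct source,
#' so the per-source counts sum to at least the edge total), and the
#' number of harmonized input entities that acquired no edge.
#'
#' @param graph a valid PropertyGraph.
#' @return a [GraphSummary-class].
#' @export
summarizeGraph <- function(graph) {
  stopifnot(is(graph, "PropertyGraph"))
  nd <- graph@nodes
  ed <- graph@edges
  by_type <- table(factor(nd$node_type, levels = nodeTypeVocabulary()))
  by_type <- by_type[by_type > 0]
  by_rel <- table(factor(ed$relation, levels = relationVocabulary()))
  by_rel <- by_rel[by_rel > 0]
  srcs <- unlist(lapply(ed$provenance, function(p) unique(p$source_name)))
  by_src <- if (length(srcs)) table(srcs) else
    table(character())
  input_keys <- graph@metadata$input_keys %||% character()
  touched <- unique(c(ed$subject_key, ed$object_key))
  unann <- sum(input_keys %in% nd$key & !(input_keys %in% touched))
  toNamedInt <- function(t) {
    v <- as.integer(t)
    names(v) <- names(t)
    v
  }
  new("GraphSummary",
      node_count_total = nrow(nd), edge_count_total = nrow(ed),
      nodes_by_type = toNamedInt(by_type),
      edges_by_relation = toNamedInt(by_rel),
      edges_by_source = toNamedInt(by_src),
      unannotated_input_entities = as.integer(unann))
}

summaryToList <- function(summary) {
  list(node_count_total = summary@node_count_total,
       edge_count_total = summary@edge_count_total,
       nodes_by_type = as.list(summary@nodes_by_type),
       edges_by_relation = as.list(summary@edges_by_relation),
       edges_by_source = as.list(summary@edges_by_source),
       unannotated_input_entities = summary@unannotated_input_entities)
}

#' Export a graph summary
#'
#' @param summary a GraphSummary.
#' @param path output path; `.json` writes JSON, anything else a
#'   two-column TSV of (measure, value).
#' @return the path, invisibly.
#' @export
writeSummary <- function(summary, path) {
  if (grepl("\\.json$", path)) {
    writeLines(as.character(jsonlite::toJSON(summaryToList(summary),
                                             auto_unbox = TRUE,
                                             pretty = TRUE)),
               path, useBytes = TRUE)
  } else {
    l <- summaryToList(summary)
    rows <- list()
    for (nm in names(l)) {
      v <- l[[nm]]
      if (is.list(v)) {
        for (k in names(v))
          rows[[length(rows) + 1L]] <- c(paste(nm, k, sep = "."),
                                         as.character(v[[k]]))
      } else rows[[length(rows) + 1L]] <- c(nm, as.character(v))
    }
    m <- do.call(rbind, rows)
    utils::write.table(data.frame(measure = m[, 1L], value = m[, 2L]),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Extract a context subgraph
#'
#' Induces the subgraph on all nodes within `hops` undirected steps of
#' any anchor (edge direction is ignored for neighborhood expansion but
#' preserved in the output), then applies optional node-type and
#' relation filters. The result is itself a valid property graph with
#' provenance intact.
#'
#' @param graph a valid PropertyGraph.
#' @param anchors character vector of node keys present in the graph.
#' @param hops non-negative integer neighborhood radius.
#' @param node_type_filter optional character vector; nodes of other
#'   types are dropped (anchors included).
#' @param relation_filter optional character vector; edges with other
#'   relations are dropped.
#' @return a PropertyGraph.
#' @export
extractSubgraph <- function(graph, anchors, hops,
                            node_type_filter = NULL,
                            relation_filter = NULL) {
  stopifnot(is(graph, "PropertyGraph"), hops >= 0)
  nd <- graph@nodes
  ed <- graph@edges
  missing_a <- setdiff(anchors, nd$key)
  if (length(missing_a))
    stopf("unknown anchor key(s): %s", paste(missing_a, collapse = ", "),
          class = "ckg_lookup_error")

  frontier <- unique(anchors)
  reached <- frontier
  h <- 0L
  while (h < hops && length(frontier)) {
    nbr <- c(ed$object_key[ed$subject_key %in% frontier],
             ed$subject_key[ed$object_key %in% frontier])
    frontier <- setdiff(unique(nbr), reached)
    reached <- c(reached, frontier)
    h <- h + 1L
  }

  keep_nodes <- nd$key %in% reached
  if (!is.null(node_type_filter))
    keep_nodes <- keep_nodes & nd$node_type %in% node_type_filter
  nd2 <- nd[keep_nodes, , drop = FALSE]
  rownames(nd2) <- NULL

  keep_edges <- ed$subject_key %in% nd2$key & ed$object_key %in% nd2$key
  if (!is.null(relation_filter))
    keep_edges <- keep_edges & ed$relation %in% relation_filter
  ed2 <- ed[keep_edges, , drop = FALSE]
  rownames(ed2) <- NULL

  meta <- graph@metadata
  if (!is.null(meta$input_keys))
    meta$input_keys <- intersect(meta$input_keys, nd2$key)
  new("PropertyGraph", nodes = nd2, edges = ed2, metadata = meta)
}

trainingIncidence <- function(catalog = defaultCatalog()) {
  edgeCategoriesFor(catalog, catalog$name)
}

#' Export labelled triples for link-prediction training
#'
#' One positive row (label 1) per graph edge, plus
#' `floor(negative_ratio * edges)` negatives (label 0) sampled uniformly
#' from the type-compatible non-edges: (head, relation, tail)
#' combinations whose (head type, relation, tail type) occurs in the
#' source-catalog incidence and which are not present as edges. Negative
#' sampling is deterministic for a fixed seed and never duplicates a
#' positive.
#'
#' @param graph a valid PropertyGraph.
#' @param negative_ratio non-negative real.
#' @param seed integer sampling key.
#' @param incidence data.frame (subject_type, relation, object_type);
#'   defaults to the union over the full catalog.
#' @return data.frame (head, relation, tail, label).
#' @export
exportTrainingTriples <- function(graph, negative_ratio = 1, seed = 1,
                                  incidence = trainingIncidence()) {
  stopifnot(is(graph, "PropertyGraph"), negative_ratio >= 0)
  ed <- graph@edges
  nd <- graph@nodes
  pos <- data.frame(head = ed$subject_key, relation = ed$relation,
                    tail = ed$object_key, label = 1L,
                    stringsAsFactors = FALSE)
  n_neg <- floor(negative_ratio * nrow(ed))
  if (n_neg == 0) return(pos)

  pos_key <- paste(pos$head, pos$relation, pos$tail, sep = "\r")
  cand <- list()
  for (i in seq_len(nrow(incidence))) {
    heads <- nd$key[nd$node_type == incidence$subject_type[i]]
    tails <- nd$key[nd$node_type == incidence$object_type[i]]
    if (!length(heads) || !length(tails)) next
    g <- expand.grid(head = heads, tail = tails,
                     stringsAsFactors = FALSE)
    g$relation <- incidence$relation[i]
    if (incidence$relation[i] != "interacts_with")
      g <- g[g$head != g$tail, , drop = FALSE]
    cand[[length(cand) + 1L]] <- g[, c("head", "relation", "tail")]
  }
  cand <- if (length(cand)) unique(do.call(rbind, cand)) else
    data.frame(head = character(), relation = character(),
               tail = character(), stringsAsFactors = FALSE)
  ckey <- paste(cand$head, cand$relation, cand$tail, sep = "\r")
  cand <- cand[!(ckey %in% pos_key), , drop = FALSE]
  if (n_neg > nrow(cand))
    stopf(paste0("requested %d negatives but only %d type-compatible ",
                 "non-edges exist"), n_neg, nrow(cand),
          class = "ckg_infeasible_error")
  # deterministic uniform sample: rank candidates by a hash keyed on the
  # seed and take the smallest ranks
  u <- vapply(seq_len(nrow(cand)), function(i)
    hashUnit(seed, cand$head[i], cand$relation[i], cand$tail[i]),
    numeric(1))
  take <- orderC(u)[seq_len(n_neg)]
  neg <- cand[take, , drop = FALSE]
  neg <- neg[orderC(neg$head, neg$relation, neg$tail), , drop = FALSE]
  neg$label <- 0L
  out <- rbind(pos, neg)
  rownames(out) <- NULL
  out
}

#' Plot summary bar charts
#'
#' Writes three PNG bar charts (nodes by type, edges by relation, edges
#' by source) into `dir`.
#'
#' @param summary a GraphSummary.
#' @param dir output directory (created if absent).
#' @return character vector of the three file paths, invisibly.
#' @export
plotSummary <- function(summary, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE,
                                      showWarnings = FALSE)
  if (!ok || !dir.exists(dir))
    stopf("cannot create plot directory '%s'", dir, class = "ckg_io_error")
  panels <- list(nodes_by_type = summary@nodes_by_type,
                 edges_by_relation = summary@edges_by_relation,
                 edges_by_source = summary@edges_by_source)
  paths <- character()
  for (nm in names(panels)) {
    p <- file.path(dir, paste0(nm, ".png"))
    grDevices::png(p, width = 800, height = 500)
    v <- panels[[nm]]
    if (!length(v)) {
      graphics::plot.new()
      graphics::title(main = paste(nm, "(empty)"))
    } else {
      graphics::par(mar = c(9, 4, 3, 1))
      graphics::barplot(v, las = 2, main = gsub("_", " ", nm),
                        ylab = "count", col = "steelblue")
    }
    grDevices::dev.off()
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Export training triples as TSV
#'
#' @param triples data.frame from [exportTrainingTriples()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTrainingTriples <- function(triples, path) {
  utils::write.table(triples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
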