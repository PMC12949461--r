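flattenAttributes <- function(attrs, where) {
  out <- list()
  for (an in names(attrs)) {
    v <- attrs[[an]]
    if (!is.atomic(v) || is.list(v))
      stopf("attribute '%s' on %s is not a JSON scalar or list of scalars",
            an, where, class = "ckg_serialization_error")
    out[[an]] <- v
  }
  out
}

joinProvenance <- function(p) {
  paste(sprintf("%s@%s@%s", p$source_name, p$source_version,
                p$retrieval_date), collapse = "|")
}

#' Serialize a property graph to Cytoscape-style JSON
#'
#' Writes the plain elements document (`nodes` / `edges` arrays) that
#' Cytoscape imports: one node element per graph node with all
#' attributes flattened into `data`, one edge element per edge with
#' source, target, relation, and provenance serialized as a
#' `|`-delimited list. Elements are sorted by key / triple so repeated
#' exports of the same graph are byte-identical.
#'
#' @param graph a valid PropertyGraph.
#' @param path optional output file (`.cyjs`); when NULL the JSON text
#'   is returned.
#' @return JSON text (invisibly when written to file).
#' @export
toCytoscapeJson <- function(graph, path = NULL) {
  stopifnot(is(graph, "PropertyGraph"))
  nd <- graph@nodes
  ed <- graph@edges

  node_elems <- lapply(orderC(nd$key), function(i) {
    data <- c(list(id = nd$key[i], node_type = nd$node_type[i],
                   label = nd$label[i]),
              flattenAttributes(nd$attributes[[i]],
                                paste("node", nd$key[i])))
    xr <- nd$xrefs[[i]]
    if (length(xr))
      data$xrefs <- paste(names(xr), xr, sep = ":", collapse = "|")
    list(data = data)
  })
  ord <- orderC(ed$subject_key, ed$relation, ed$object_key)
  edge_elems <- lapply(ord, function(i) {
    data <- c(list(id = paste(ed$subject_key[i], ed$relation[i],
                              ed$object_key[i], sep = "|"),
                   source = ed$subject_key[i],
                   target = ed$object_key[i],
                   relation = ed$relation[i],
                   provenance = joinProvenance(ed$provenance[[i]])),
              flattenAttributes(ed$attributes[[i]],
                                sprintf("edge %s-%s-%s", ed$subject_key[i],
                                        ed$relation[i], ed$object_key[i])))
    list(data = data)
  })
  doc <- list(format_version = "1.0",
              generated_by = "ContextKG",
              elements = list(nodes = node_elems, edges = edge_elems))
  txt <- as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                       pretty = TRUE, null = "null"))
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}
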