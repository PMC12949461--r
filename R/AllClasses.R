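#' @import methods
NULL

emptyHarmonizedRows <- function() {
  data.frame(canonical_key = character(), raw_identifier = character(),
             declared_namespace = character(), entity_kind = character(),
             effect_size = numeric(), significance = numeric(),
             stringsAsFactors = FALSE)
}

emptyUnmapped <- function() {
  data.frame(raw_identifier = character(), declared_namespace = character(),
             entity_kind = character(), reason = character(),
             stringsAsFactors = FALSE)
}

emptyNodeTable <- function() {
  d <- data.frame(key = character(), node_type = character(),
                  label = character(), stringsAsFactors = FALSE)
  d$xrefs <- list()
  d$attributes <- list()
  d
}

emptyEdgeTable <- function() {
  d <- data.frame(subject_key = character(), relation = character(),
                  object_key = character(), stringsAsFactors = FALSE)
  d$provenance <- list()
  d$attributes <- list()
  d
}

emptyProvenance <- function() {
  data.frame(source_name = character(), source_version = character(),
             retrieval_date = character(), stringsAsFactors = FALSE)
}

#' HarmonizedTable: inputs after identifier mapping
#'
#' One row per canonical entity (key `"NAMESPACE:accession"`), carrying
#' the original input record, all reachable cross-references, and any
#' differential-expression statistics. Records that no mapping chain
#' could bring into the target namespace sit in `unmapped` with a reason,
#' so every distinct input record lands in exactly one of the two tables.
#'
#' @slot rows data.frame with columns canonical_key, raw_identifier,
#'   declared_namespace, entity_kind, effect_size, significance and a
#'   list-column `xrefs` (named character vectors, namespace -> accession).
#' @slot unmapped data.frame of unmappable records with a `reason` column.
#' @slot provenance single string naming the mapping source and version.
#' @export
setClass("HarmonizedTable",
  representation(rows = "data.frame", unmapped = "data.frame",
                 provenance = "character"),
  prototype(rows = emptyHarmonizedRows(), unmapped = emptyUnmapped(),
            provenance = "none"),
  validity = function(object) {
    msgs <- character()
    if (anyDuplicated(object@rows$canonical_key))
      msgs <- c(msgs, "duplicate canonical keys in rows")
    need <- c("canonical_key", "raw_identifier", "entity_kind")
    miss <- setdiff(need, names(object@rows))
    if (length(miss))
      msgs <- c(msgs, paste("rows missing columns:", paste(miss, collapse = ", ")))
    p <- object@rows$significance
    if (length(p) && any(!is.na(p) & (p < 0 | p > 1)))
      msgs <- c(msgs, "significance values outside [0,1]")
    if (length(msgs)) msgs else TRUE
  }
)

#' PropertyGraph: a typed, provenance-tracked knowledge graph
#'
#' Nodes carry a canonical key, one of the 18 closed node types, a display
#' label, cross-references and flat attributes. Edges are directed,
#' carry one of the 10 closed relations, and each edge holds a non-empty
#' provenance table (source name, version, retrieval date) accumulated
#' over all sources that asserted the same (subject, relation, object)
#' triple. Use [buildGraph()] to construct and [validateGraph()] for a
#' full invariant report.
#'
#' @slot nodes data.frame: key, node_type, label + list-columns xrefs,
#'   attributes.
#' @slot edges data.frame: subject_key, relation, object_key +
#'   list-columns provenance (data.frames), attributes.
#' @slot metadata list with elements `query_metadata` (data.frame) and
#'   `harmonization` (character provenance string).
#' @export
setClass("PropertyGraph",
  representation(nodes = "data.frame", edges = "data.frame",
                 metadata = "list"),
  prototype(nodes = emptyNodeTable(), edges = emptyEdgeTable(),
            metadata = list(query_metadata = NULL, harmonization = "none")),
  validity = function(object) {
    # structural checks only; the full semantic report is validateGraph()
    msgs <- character()
    if (!all(c("key", "node_type", "label") %in% names(object@nodes)))
      msgs <- c(msgs, "nodes table lacks key/node_type/label columns")
    if (!all(c("subject_key", "relation", "object_key") %in% names(object@edges)))
      msgs <- c(msgs, "edges table lacks subject_key/relation/object_key columns")
    if (length(msgs)) msgs else TRUE
  }
)

#' GraphSummary: counts over a PropertyGraph
#'
#' @slot node_count_total,edge_count_total integer totals.
#' @slot nodes_by_type,edges_by_relation,edges_by_source named integer
#'   vectors; a multi-provenance edge counts once per distinct source, so
#'   `edges_by_source` sums to at least `edge_count_total`.
#' @slot unannotated_input_entities number of harmonized input entities
#'   that acquired no edge.
#' @export
setClass("GraphSummary",
  representation(node_count_total = "integer", edge_count_total = "integer",
                 nodes_by_type = "integer", edges_by_relation = "integer",
                 edges_by_source = "integer",
                 unannotated_input_entities = "integer"))

#' @describeIn PropertyGraph node table accessor
#' @param x a PropertyGraph
#' @export
graphNodes <- function(x) {
  stopifnot(is(x, "PropertyGraph"))
  x@nodes
}

#' @describeIn PropertyGraph edge table accessor
#' @export
graphEdges <- function(x) {
  stopifnot(is(x, "PropertyGraph"))
  x@edges
}

#' @describeIn PropertyGraph build metadata accessor
#' @export
buildMetadata <- function(x) {
  stopifnot(is(x, "PropertyGraph"))
  x@metadata
}

#' @describeIn HarmonizedTable mapped rows accessor
#' @param x a HarmonizedTable
#' @export
harmonizedRows <- function(x) {
  stopifnot(is(x, "HarmonizedTable"))
  x@rows
}

#' @describeIn HarmonizedTable unmapped records accessor
#' @export
unmappedRecords <- function(x) {
  stopifnot(is(x, "HarmonizedTable"))
  x@unmapped
}

#' @describeIn HarmonizedTable mapping provenance accessor
#' @export
mappingProvenance <- function(x) {
  stopifnot(is(x, "HarmonizedTable"))
  x@provenance
}

setMethod("show", "HarmonizedTable", function(object) {
  cat(sprintf("HarmonizedTable: %d mapped, %d unmapped (mapping: %s)\n",
              nrow(object@rows), nrow(object@unmapped), object@provenance))
  if (nrow(object@rows)) {
    head_keys <- utils::head(object@rows$canonical_key, 5)
    cat("  keys:", paste(head_keys, collapse = ", "),
        if (nrow(object@rows) > 5) "..." else "", "\n")
  }
})

setMethod("show", "PropertyGraph", function(object) {
  tt <- table(object@nodes$node_type)
  cat(sprintf("PropertyGraph: %d nodes, %d edges\n",
              nrow(object@nodes), nrow(object@edges)))
  if (length(tt))
    cat("  node types:", paste(sprintf("%s(%d)", names(tt), tt),
                               collapse = ", "), "\n")
  rr <- table(object@edges$relation)
  if (length(rr))
    cat("  relations:", paste(sprintf("%s(%d)", names(rr), rr),
                              collapse = ", "), "\n")
})

setMethod("show", "GraphSummary", function(object) {
  cat(sprintf("GraphSummary: %d nodes, %d edges, %d unannotated inputs\n",
              object@node_count_total, object@edge_count_total,
              object@unannotated_input_entities))
})
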