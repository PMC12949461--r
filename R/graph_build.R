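entityKindToNodeType <- function(kind) {
  switch(kind, gene = "gene", metabolite = "compound",
         stopf("no node type for entity kind '%s'", kind,
               class = "ckg_vocabulary_error"))
}

#' Build a property graph from harmonized entities and annotation rows
#'
#' Every harmonized input entity becomes a node even when unannotated;
#' each annotation row contributes its object node (created or merged by
#' canonical key) and one directed edge. Edge identity is the
#' (subject, relation, object) triple: the same assertion from several
#' sources merges into one edge whose provenance accumulates one entry
#' per source run, so no information about origin is lost. DEA effect
#' size and significance are copied from the table onto the gene nodes.
#' Output ordering is canonicalized (nodes by key, edges by triple), so
#' identical inputs produce structurally identical graphs regardless of
#' row order.
#'
#' Node merging: a key asserted under two different node types is a
#' conflict error naming the sources involved; colliding scalar
#' attributes resolve last-writer-wins with a warning, except DEA
#' statistics, which raise.
#'
#' @param table a [HarmonizedTable-class].
#' @param rows annotation rows from [annotateTable()] (may be empty).
#' @param metadata query-metadata data.frame from [annotateTable()].
#' @return a [PropertyGraph-class].
#' @export
buildGraph <- function(table, rows = emptyAnnotationRows(),
                       metadata = emptyQueryMetadata()) {
  stopifnot(is(table, "HarmonizedTable"))
  hr <- harmonizedRows(table)

  nodes <- new.env(parent = emptyenv())
  addNode <- function(key, node_type, label, xrefs = character(),
                      attributes = list(), origin = "input") {
    assertNodeType(node_type)
    if (is.na(label) || !nzchar(label)) label <- key
    cur <- nodes[[key]]
    if (is.null(cur)) {
      nodes[[key]] <- list(key = key, node_type = node_type, label = label,
                           xrefs = dedupXrefs(xrefs),
                           attributes = attributes,
                           origins = origin)
      return(invisible(NULL))
    }
    if (!identical(cur$node_type, node_type))
      stopf("node type conflict for %s: '%s' (from %s) vs '%s' (from %s)",
            key, cur$node_type, paste(cur$origins, collapse = ","),
            node_type, origin, class = "ckg_conflict_error")
    if (!is.na(label) && nzchar(label) &&
        (is.na(cur$label) || !nzchar(cur$label)))
      cur$label <- label
    cur$xrefs <- dedupXrefs(c(cur$xrefs, xrefs))
    for (an in names(attributes)) {
      old <- cur$attributes[[an]]
      newv <- attributes[[an]]
      if (!is.null(old) && !identical(old, newv)) {
        if (an %in% c("effect_size", "significance"))
          stopf("conflicting DEA statistic '%s' for node %s", an, key,
                class = "ckg_conflict_error")
        warnf("attribute '%s' on node %s overwritten (%s -> %s)",
              an, key, paste(old, collapse = ","),
              paste(newv, collapse = ","))
      }
      cur$attributes[[an]] <- newv
    }
    cur$origins <- unique(c(cur$origins, origin))
    nodes[[key]] <- cur
    invisible(NULL)
  }

  for (i in seq_len(nrow(hr))) {
    attrs <- list()
    if (!is.na(hr$effect_size[i])) attrs$effect_size <- hr$effect_size[i]
    if (!is.na(hr$significance[i])) attrs$significance <- hr$significance[i]
    xr <- hr$xrefs[[i]] %||% character()
    # the canonical key itself is implicit, not a cross-reference
    if (length(xr))
      xr <- xr[canonicalKey(names(xr), xr) != hr$canonical_key[i]]
    addNode(hr$canonical_key[i],
            entityKindToNodeType(hr$entity_kind[i]),
            label = hr$raw_identifier[i],
            xrefs = xr, attributes = attrs, origin = "input")
  }
  input_keys <- hr$canonical_key

  if (nrow(rows)) {
    assertRelation(rows$relation)
    assertNodeType(rows$object_type)
    meta_by_ref <- metadata[match(rows$metadata_ref, metadata$metadata_ref), ,
                            drop = FALSE]
    src_of <- ifelse(is.na(rows$metadata_ref), "unattributed",
                     meta_by_ref$source_name)
    for (i in seq_len(nrow(rows))) {
      subj <- rows$subject_key[i]
      known <- !is.null(nodes[[subj]])
      if (!known) {
        if (is.na(rows$subject_type[i]))
          stopf("annotation row %d has unknown subject %s", i, subj,
                class = "ckg_integrity_error")
        addNode(subj, rows$subject_type[i],
                label = rows$subject_label[i], origin = src_of[i])
      }
      addNode(rows$object_key[i], rows$object_type[i],
              label = rows$object_label[i],
              attributes = rows$object_attributes[[i]] %||% list(),
              origin = src_of[i])
    }
  }

  prov_for <- function(ref) {
    j <- match(ref, metadata$metadata_ref)
    if (is.na(j))
      return(data.frame(source_name = "unattributed",
                        source_version = "unknown",
                        retrieval_date = "unknown",
                        stringsAsFactors = FALSE))
    data.frame(source_name = metadata$source_name[j],
               source_version = metadata$source_version[j],
               retrieval_date = metadata$retrieval_date[j],
               stringsAsFactors = FALSE)
  }

  edges <- new.env(parent = emptyenv())
  if (nrow(rows)) {
    for (i in seq_len(nrow(rows))) {
      ekey <- paste(rows$subject_key[i], rows$relation[i],
                    rows$object_key[i], sep = "\r")
      prov <- prov_for(rows$metadata_ref[i])
      attrs <- rows$edge_attributes[[i]] %||% list()
      attrs <- attrs[!vapply(attrs, function(v)
        length(v) == 1L && is.na(v), logical(1))]
      cur <- edges[[ekey]]
      if (is.null(cur)) {
        edges[[ekey]] <- list(subject_key = rows$subject_key[i],
                              relation = rows$relation[i],
                              object_key = rows$object_key[i],
                              provenance = prov, attributes = attrs)
      } else {
        cur$provenance <- rbind(cur$provenance, prov)
        for (an in names(attrs)) {
          old <- cur$attributes[[an]]
          if (!is.null(old) && !identical(old, attrs[[an]]))
            warnf("edge attribute '%s' on %s %s %s overwritten",
                  an, rows$subject_key[i], rows$relation[i],
                  rows$object_key[i])
          cur$attributes[[an]] <- attrs[[an]]
        }
        edges[[ekey]] <- cur
      }
    }
  }

  assemblePropertyGraph(nodes, edges,
                        metadata = list(query_metadata = metadata,
                                        harmonization = mappingProvenance(table),
                                        input_keys = input_keys))
}

# canonicalize environments of node/edge records into the S4 container
assemblePropertyGraph <- function(nodes, edges, metadata) {
  nkeys <- sortC(ls(nodes))
  nd <- emptyNodeTable()
  if (length(nkeys)) {
    recs <- lapply(nkeys, function(k) nodes[[k]])
    nd <- data.frame(key = nkeys,
                     node_type = vapply(recs, `[[`, character(1), "node_type"),
                     label = vapply(recs, function(r)
                       as.character(r$label %||% r$key), character(1)),
                     stringsAsFactors = FALSE)
    nd$xrefs <- lapply(recs, function(r) r$xrefs %||% character())
    nd$attributes <- lapply(recs, function(r) sortAttributes(r$attributes))
  }
  ekeys <- sortC(ls(edges))
  ed <- emptyEdgeTable()
  if (length(ekeys)) {
    recs <- lapply(ekeys, function(k) edges[[k]])
    ed <- data.frame(
      subject_key = vapply(recs, `[[`, character(1), "subject_key"),
      relation = vapply(recs, `[[`, character(1), "relation"),
      object_key = vapply(recs, `[[`, character(1), "object_key"),
      stringsAsFactors = FALSE)
    ed$provenance <- lapply(recs, function(r) canonicalProvenance(r$provenance))
    ed$attributes <- lapply(recs, function(r) sortAttributes(r$attributes))
    ord <- orderC(ed$subject_key, ed$relation, ed$object_key)
    ed <- ed[ord, , drop = FALSE]
    rownames(ed) <- NULL
  }
  new("PropertyGraph", nodes = nd, edges = ed, metadata = metadata)
}

canonicalProvenance <- function(p) {
  if (is.null(p) || !nrow(p)) return(emptyProvenance())
  p <- unique(p)
  p <- p[orderC(p$source_name, p$source_version, p$retrieval_date), ,
         drop = FALSE]
  rownames(p) <- NULL
  p
}

sortAttributes <- function(a) {
  if (is.null(a) || !length(a)) return(structure(list(), names = character()))
  a[sortC(names(a))]
}

#' Inject a context node into an existing graph
#'
#' Adds (or merges by key) one node — typically a disease anchoring the
#' biological context, e.g. a long-COVID node `UMLS:C5433293` backed by
#' literature curation — and one edge per supplied link connecting
#' existing entities to it. Links point from the existing entity to the
#' context node (gene `associated_with` disease).
#'
#' @param graph a PropertyGraph.
#' @param key canonical key of the context node.
#' @param node_type member of [nodeTypeVocabulary()].
#' @param label display label.
#' @param links data.frame with columns entity_key, relation (may be
#'   empty / NULL for a node-only insertion).
#' @param provenance_tag source name recorded on the created edges.
#' @param provenance_version,provenance_date provenance fields for the
#'   created edges.
#' @return the updated PropertyGraph.
#' @export
addContextNode <- function(graph, key, node_type, label,
                           links = NULL, provenance_tag = "curated",
                           provenance_version = "manual",
                           provenance_date = "unknown") {
  stopifnot(is(graph, "PropertyGraph"))
  assertNodeType(node_type)
  nd <- graph@nodes
  ed <- graph@edges
  if (is.null(links))
    links <- data.frame(entity_key = character(), relation = character(),
                        stringsAsFactors = FALSE)
  missing_ent <- setdiff(links$entity_key, nd$key)
  if (length(missing_ent))
    stopf("context link refers to missing entity key(s): %s",
          paste(missing_ent, collapse = ", "),
          class = "ckg_integrity_error")
  if (nrow(links)) assertRelation(links$relation)

  i <- match(key, nd$key)
  if (is.na(i)) {
    add <- data.frame(key = key, node_type = node_type, label = label,
                      stringsAsFactors = FALSE)
    add$xrefs <- list(character())
    add$attributes <- list(structure(list(), names = character()))
    nd <- rbind(nd, add)
    nd <- nd[orderC(nd$key), , drop = FALSE]
    rownames(nd) <- NULL
  } else if (!identical(nd$node_type[i], node_type)) {
    stopf("node type conflict for context node %s: '%s' vs '%s'",
          key, nd$node_type[i], node_type, class = "ckg_conflict_error")
  }

  prov <- data.frame(source_name = provenance_tag,
                     source_version = provenance_version,
                     retrieval_date = provenance_date,
                     stringsAsFactors = FALSE)
  for (j in seq_len(nrow(links))) {
    s <- links$entity_key[j]; r <- links$relation[j]
    hit <- which(ed$subject_key == s & ed$relation == r &
                   ed$object_key == key)
    if (length(hit)) {
      ed$provenance[[hit]] <- canonicalProvenance(
        rbind(ed$provenance[[hit]], prov))
    } else {
      add <- data.frame(subject_key = s, relation = r, object_key = key,
                        stringsAsFactors = FALSE)
      add$provenance <- list(prov)
      add$attributes <- list(structure(list(), names = character()))
      ed <- rbind(ed, add)
    }
  }
  if (nrow(ed)) {
    ed <- ed[orderC(ed$subject_key, ed$relation, ed$object_key), ,
             drop = FALSE]
    rownames(ed) <- NULL
  }
  new("PropertyGraph", nodes = nd, edges = ed, metadata = graph@metadata)
}

#' Full invariant report for a property graph
#'
#' Checks the semantic invariants of the container: unique node keys,
#' edge endpoints present, non-empty per-edge provenance, closed
#' node-type and relation vocabularies, no duplicate
#' (subject, relation, object) triples, self-loops only for
#' interacts_with, and attribute values that are scalars or vectors of
#' scalars (hence serializable to all three export formats).
#'
#' @param graph a PropertyGraph.
#' @return data.frame of violations (rule, detail); zero rows iff the
#'   graph is valid.
#' @export
validateGraph <- function(graph) {
  stopifnot(is(graph, "PropertyGraph"))
  v <- list()
  bad <- function(rule, detail)
    v[[length(v) + 1L]] <<- data.frame(rule = rule, detail = detail,
                                       stringsAsFactors = FALSE)
  nd <- graph@nodes; ed <- graph@edges

  dup <- nd$key[duplicated(nd$key)]
  for (k in unique(dup)) bad("unique_node_key", k)
  for (t in setdiff(unique(nd$node_type), nodeTypeVocabulary()))
    bad("node_type_vocabulary", t)
  for (r in setdiff(unique(ed$relation), relationVocabulary()))
    bad("relation_vocabulary", r)
  for (k in setdiff(unique(c(ed$subject_key, ed$object_key)), nd$key))
    bad("dangling_endpoint", k)

  triple <- paste(ed$subject_key, ed$relation, ed$object_key, sep = " ")
  for (t in unique(triple[duplicated(triple)])) bad("duplicate_edge", t)

  for (i in seq_len(nrow(ed))) {
    p <- ed$provenance[[i]]
    if (is.null(p) || !nrow(p)) bad("empty_provenance", triple[i])
    if (ed$subject_key[i] == ed$object_key[i] &&
        ed$relation[i] != "interacts_with")
      bad("self_loop", triple[i])
  }
  okScalar <- function(x) is.atomic(x) && !is.list(x)
  for (i in seq_len(nrow(nd))) {
    a <- nd$attributes[[i]]
    for (an in names(a)) if (!okScalar(a[[an]]))
      bad("unserializable_attribute", paste(nd$key[i], an))
  }
  out <- if (length(v)) do.call(rbind, v)
         else data.frame(rule = character(), detail = character(),
                         stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
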