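rdfIris <- function() {
  list(
    rdf_type = "http://www.w3.org/1999/02/22-rdf-syntax-ns#type",
    rdf_statement = "http://www.w3.org/1999/02/22-rdf-syntax-ns#Statement",
    rdf_subject = "http://www.w3.org/1999/02/22-rdf-syntax-ns#subject",
    rdf_predicate = "http://www.w3.org/1999/02/22-rdf-syntax-ns#predicate",
    rdf_object = "http://www.w3.org/1999/02/22-rdf-syntax-ns#object",
    rdfs_label = "http://www.w3.org/2000/01/rdf-schema#label",
    skos_exact_match = "http://www.w3.org/2004/02/skos/core#exactMatch",
    dcterms_title = "http://purl.org/dc/terms/title",
    dcterms_source = "http://purl.org/dc/terms/source",
    pav_version = "http://purl.org/pav/version",
    pav_retrieved_on = "http://purl.org/pav/retrievedOn",
    void_dataset = "http://rdfs.org/ns/void#Dataset",
    void_vocabulary = "http://rdfs.org/ns/void#vocabulary",
    sio_ns = "http://semanticscience.org/resource/",
    sio_has_part = "http://semanticscience.org/resource/SIO_000028",
    sio_has_measurement_value = "http://semanticscience.org/resource/SIO_000216",
    sio_has_value = "http://semanticscience.org/resource/SIO_000300",
    sio_measurement = "http://semanticscience.org/resource/SIO_000070",
    obo_ns = "http://purl.obolibrary.org/obo/",
    xsd_double = "http://www.w3.org/2001/XMLSchema#double",
    xsd_boolean = "http://www.w3.org/2001/XMLSchema#boolean"
  )
}

#' The node-type / relation to ontology-term mapping
#'
#' Loads the shipped correspondence from the 18 node types to ontology
#' classes (SIO, OBO, AOP ontology) and from the 10 relations to
#' predicates (Relation Ontology for regulation, BFO part_of, a SIO
#' association class for associated_with, which is reified as an
#' association node rather than a direct triple). The mapping is
#' configuration: edit the JSON file or pass a modified list to
#' [toRdf()].
#'
#' @param path JSON mapping file; defaults to the copy shipped with the
#'   package.
#' @return list with `node_classes` (named over all 18 types) and
#'   `relation_predicates` (named over all 10 relations).
#' @export
defaultRdfMapping <- function(path = system.file("extdata",
                                                 "rdf_mapping.json",
                                                 package = "ContextKG")) {
  m <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  m$node_classes <- unlist(m$node_classes)
  m$relation_predicates <- unlist(m$relation_predicates)
  missing_t <- setdiff(nodeTypeVocabulary(), names(m$node_classes))
  missing_r <- setdiff(relationVocabulary(), names(m$relation_predicates))
  if (length(missing_t) || length(missing_r))
    stopf("RDF mapping is not total: missing %s",
          paste(c(missing_t, missing_r), collapse = ", "),
          class = "ckg_config_error")
  ok_iri <- function(x) grepl("^https?://\\S+$", x)
  bad <- c(m$node_classes, m$relation_predicates)
  bad <- bad[!ok_iri(bad)]
  if (length(bad))
    stopf("invalid IRI(s) in RDF mapping: %s", paste(bad, collapse = ", "),
          class = "ckg_config_error")
  m
}

#' Entity IRI policy
#'
#' Identifiers-registry-style rule: an entity with canonical key
#' `NS:accession` gets the IRI `<base>/id/<NS>/<accession>` (both parts
#' percent-encoded), which is injective over distinct
#' (namespace, accession) pairs.
#'
#' @param base_iri base IRI without trailing slash.
#' @return list(base_iri, entity_iri = function(namespace, accession)).
#' @export
uriPolicy <- function(base_iri = "https://contextkg.example/kg") {
  base_iri <- sub("/+$", "", base_iri)
  enc <- function(x) utils::URLencode(x, reserved = TRUE)
  list(base_iri = base_iri,
       entity_iri = function(namespace, accession)
         paste0(base_iri, "/id/", enc(toupper(namespace)), "/",
                enc(accession)))
}

tripleRow <- function(s, p, o, kind = "iri", datatype = NA_character_) {
  data.frame(subject = s, predicate = p, object = o, object_kind = kind,
             datatype = datatype, stringsAsFactors = FALSE)
}

keyIri <- function(key, policy) {
  cur <- splitCurie(key)
  if (is.na(cur$namespace))
    return(policy$entity_iri("UNKNOWN", key))
  policy$entity_iri(cur$namespace, cur$accession)
}

# measurement-value pattern: 3 triples per numeric scalar
measurementTriples <- function(node_iri, name, value, base, iris, idx) {
  m <- paste0(node_iri, "/measurement/",
              utils::URLencode(name, reserved = TRUE),
              if (idx > 1L) paste0("/", idx) else "")
  rbind(
    tripleRow(node_iri, iris$sio_has_measurement_value, m),
    tripleRow(m, iris$rdf_type, iris$sio_measurement),
    tripleRow(m, iris$sio_has_value, sprintf("%.17g", value),
              kind = "typed_literal", datatype = iris$xsd_double))
}

attributeTriples <- function(node_iri, attrs, base, iris) {
  out <- list()
  for (an in names(attrs)) {
    v <- attrs[[an]]
    if (is.numeric(v)) {
      for (k in seq_along(v))
        out[[length(out) + 1L]] <-
          measurementTriples(node_iri, an, v[k], base, iris, k)
    } else {
      pred <- paste0(base, "/attribute/",
                     utils::URLencode(an, reserved = TRUE))
      for (k in seq_along(v))
        out[[length(out) + 1L]] <-
          tripleRow(node_iri, pred, as.character(v[k]), kind = "literal")
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# inline provenance fields; safe only on a per-entry anchor
provenanceTriples <- function(anchor, prov, iris) {
  out <- list()
  for (i in seq_len(nrow(prov))) {
    out[[length(out) + 1L]] <- rbind(
      tripleRow(anchor, iris$dcterms_source, prov$source_name[i],
                kind = "literal"),
      tripleRow(anchor, iris$pav_version, prov$source_version[i],
                kind = "literal"),
      tripleRow(anchor, iris$pav_retrieved_on, prov$retrieval_date[i],
                kind = "literal"))
  }
  do.call(rbind, out)
}

# one provenance record node per entry (4 triples each), used where a
# single anchor carries several provenance entries
provenanceRecordTriples <- function(anchor, prov, iris) {
  out <- list()
  for (i in seq_len(nrow(prov))) {
    p <- paste0(anchor, "/prov/", i)
    out[[length(out) + 1L]] <- rbind(
      tripleRow(anchor, iris$dcterms_source, p),
      tripleRow(p, iris$rdfs_label, prov$source_name[i], kind = "literal"),
      tripleRow(p, iris$pav_version, prov$source_version[i],
                kind = "literal"),
      tripleRow(p, iris$pav_retrieved_on, prov$retrieval_date[i],
                kind = "literal"))
  }
  do.call(rbind, out)
}

#' Serialize a property graph to RDF
#'
#' Each node yields a type triple, a label triple, one `skos:exactMatch`
#' triple per cross-reference, and the SIO measurement-value pattern (3
#' triples) per numeric attribute element; non-numeric attributes are
#' direct literal triples. `associated_with` edges are reified as
#' first-class association nodes (`sio:has_part` linking the two
#' participants); every other relation is a direct predicate triple with
#' an RDF-reification provenance node per provenance entry carrying the
#' source name, version and retrieval date. A fixed 4-triple dataset
#' header opens the document. Triples are emitted sorted, so
#' serialization is byte-deterministic.
#'
#' @param graph a valid PropertyGraph.
#' @param mapping [defaultRdfMapping()] or a compatible list.
#' @param policy [uriPolicy()].
#' @return data.frame of triples (subject, predicate, object,
#'   object_kind, datatype) with attribute `"turtle"` holding the
#'   serialized Turtle text.
#' @export
toRdf <- function(graph, mapping = defaultRdfMapping(),
                  policy = uriPolicy()) {
  stopifnot(is(graph, "PropertyGraph"))
  iris <- rdfIris()
  base <- policy$base_iri
  out <- list(rbind(
    tripleRow(base, iris$rdf_type, iris$void_dataset),
    tripleRow(base, iris$dcterms_title,
              "ContextKG knowledge graph", kind = "literal"),
    tripleRow(base, iris$void_vocabulary, iris$sio_ns),
    tripleRow(base, iris$void_vocabulary, iris$obo_ns)))

  nd <- graph@nodes
  for (i in seq_len(nrow(nd))) {
    ni <- keyIri(nd$key[i], policy)
    out[[length(out) + 1L]] <- rbind(
      tripleRow(ni, iris$rdf_type, mapping$node_classes[[nd$node_type[i]]]),
      tripleRow(ni, iris$rdfs_label, nd$label[i], kind = "literal"))
    xr <- nd$xrefs[[i]]
    for (k in seq_along(xr))
      out[[length(out) + 1L]] <- tripleRow(
        ni, iris$skos_exact_match,
        policy$entity_iri(names(xr)[k], xr[[k]]))
    at <- attributeTriples(ni, nd$attributes[[i]], base, iris)
    if (!is.null(at)) out[[length(out) + 1L]] <- at
  }

  ed <- graph@edges
  enc <- function(x) utils::URLencode(x, reserved = TRUE)
  for (i in seq_len(nrow(ed))) {
    s <- keyIri(ed$subject_key[i], policy)
    o <- keyIri(ed$object_key[i], policy)
    rel <- ed$relation[i]
    pred <- mapping$relation_predicates[[rel]]
    prov <- ed$provenance[[i]]
    if (rel == "associated_with") {
      a <- paste0(base, "/association/", enc(ed$subject_key[i]), "--",
                  enc(ed$object_key[i]))
      out[[length(out) + 1L]] <- rbind(
        tripleRow(a, iris$rdf_type, pred),
        tripleRow(a, iris$sio_has_part, s),
        tripleRow(a, iris$sio_has_part, o))
      out[[length(out) + 1L]] <- provenanceRecordTriples(a, prov, iris)
      at <- attributeTriples(a, ed$attributes[[i]], base, iris)
      if (!is.null(at)) out[[length(out) + 1L]] <- at
    } else {
      out[[length(out) + 1L]] <- tripleRow(s, pred, o)
      for (pi in seq_len(nrow(prov))) {
        r <- paste0(base, "/statement/", enc(ed$subject_key[i]), "--",
                    enc(rel), "--", enc(ed$object_key[i]), "/", pi)
        out[[length(out) + 1L]] <- rbind(
          tripleRow(r, iris$rdf_type, iris$rdf_statement),
          tripleRow(r, iris$rdf_subject, s),
          tripleRow(r, iris$rdf_predicate, pred),
          tripleRow(r, iris$rdf_object, o),
          provenanceTriples(r, prov[pi, , drop = FALSE], iris))
      }
      at <- attributeTriples(
        paste0(base, "/statement/", enc(ed$subject_key[i]), "--",
               enc(rel), "--", enc(ed$object_key[i]), "/1"),
        ed$attributes[[i]], base, iris)
      if (!is.null(at)) out[[length(out) + 1L]] <- at
    }
  }

  triples <- do.call(rbind, out)
  triples <- unique(triples)
  triples <- triples[orderC(triples$subject, triples$predicate,
                            triples$object), , drop = FALSE]
  rownames(triples) <- NULL
  attr(triples, "turtle") <- writeTurtle(triples)
  triples
}

escapeTurtleLiteral <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x
}

#' Render a triple table as Turtle text
#'
#' One sorted triple per line; no prefixes, full IRIs, so output is
#' trivially diffable and byte-stable.
#'
#' @param triples data.frame from [toRdf()].
#' @param path optional output `.ttl` file.
#' @return Turtle text (invisibly when written to file).
#' @export
writeTurtle <- function(triples, path = NULL) {
  obj <- character(nrow(triples))
  for (i in seq_len(nrow(triples))) {
    obj[i] <- switch(triples$object_kind[i],
      iri = sprintf("<%s>", triples$object[i]),
      literal = sprintf("\"%s\"", escapeTurtleLiteral(triples$object[i])),
      typed_literal = sprintf("\"%s\"^^<%s>",
                              escapeTurtleLiteral(triples$object[i]),
                              triples$datatype[i]),
      stopf("unknown object kind '%s'", triples$object_kind[i]))
  }
  lines <- sprintf("<%s> <%s> %s .", triples$subject, triples$predicate,
                   obj)
  txt <- paste(c(lines, ""), collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "", useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}
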