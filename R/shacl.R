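shaclIris <- function() {
  list(node_shape = "http://www.w3.org/ns/shacl#NodeShape",
       target_class = "http://www.w3.org/ns/shacl#targetClass",
       property = "http://www.w3.org/ns/shacl#property",
       path = "http://www.w3.org/ns/shacl#path",
       min_count = "http://www.w3.org/ns/shacl#minCount",
       node_kind = "http://www.w3.org/ns/shacl#nodeKind",
       iri_kind = "http://www.w3.org/ns/shacl#IRI",
       xsd_integer = "http://www.w3.org/2001/XMLSchema#integer")
}

#' Generate SHACL shapes for a graph's RDF serialization
#'
#' One `sh:NodeShape` is produced per node type actually instantiated in
#' the graph (never all 18), targeting the ontology class that
#' [toRdf()] assigns to that type. Each shape constrains the predicates
#' actually used from that class: `rdfs:label` with `sh:minCount 1`,
#' plus a property shape per cross-reference, attribute and outgoing
#' direct relation observed on nodes of the type. The RDF serialization
#' of the same graph conforms to the generated shapes by construction;
#' [validateShacl()] checks it.
#'
#' @param graph a valid PropertyGraph.
#' @param mapping RDF mapping as in [toRdf()].
#' @param policy IRI policy as in [toRdf()].
#' @return data.frame of shape triples with attribute `"turtle"`.
#' @export
generateShacl <- function(graph, mapping = defaultRdfMapping(),
                          policy = uriPolicy()) {
  stopifnot(is(graph, "PropertyGraph"))
  iris <- rdfIris()
  sh <- shaclIris()
  base <- policy$base_iri
  nd <- graph@nodes
  ed <- graph@edges
  out <- list()
  types <- sortC(unique(nd$node_type))
  for (tp in types) {
    keys <- nd$key[nd$node_type == tp]
    shape <- paste0(base, "/shape/", tp)
    out[[length(out) + 1L]] <- rbind(
      tripleRow(shape, iris$rdf_type, sh$node_shape),
      tripleRow(shape, sh$target_class, mapping$node_classes[[tp]]))
    # predicates used from this class
    preds <- c(iris$rdfs_label)
    min_counts <- c(1L)
    idx <- nd$node_type == tp
    if (any(lengths(nd$xrefs[idx]) > 0)) {
      preds <- c(preds, iris$skos_exact_match)
      min_counts <- c(min_counts, 0L)
    }
    attr_names <- sortC(unique(unlist(lapply(nd$attributes[idx], names))))
    for (an in attr_names) {
      vals <- lapply(nd$attributes[idx], `[[`, an)
      vals <- Filter(Negate(is.null), vals)
      if (all(vapply(vals, is.numeric, logical(1)))) {
        p <- iris$sio_has_measurement_value
      } else {
        p <- paste0(base, "/attribute/",
                    utils::URLencode(an, reserved = TRUE))
      }
      if (!p %in% preds) { preds <- c(preds, p); min_counts <- c(min_counts, 0L) }
    }
    rels <- sortC(unique(ed$relation[ed$subject_key %in% keys]))
    rels <- setdiff(rels, "associated_with")  # reified, no direct triple
    for (r in rels) {
      p <- mapping$relation_predicates[[r]]
      if (!p %in% preds) { preds <- c(preds, p); min_counts <- c(min_counts, 0L) }
    }
    for (k in seq_along(preds)) {
      pnode <- paste0(shape, "/prop/", k)
      out[[length(out) + 1L]] <- rbind(
        tripleRow(shape, sh$property, pnode),
        tripleRow(pnode, sh$path, preds[k]),
        tripleRow(pnode, sh$min_count, as.character(min_counts[k]),
                  kind = "typed_literal", datatype = sh$xsd_integer))
    }
  }
  shapes <- if (length(out)) do.call(rbind, out) else
    data.frame(subject = character(), predicate = character(),
               object = character(), object_kind = character(),
               datatype = character(), stringsAsFactors = FALSE)
  if (nrow(shapes)) {
    shapes <- unique(shapes)
    shapes <- shapes[orderC(shapes$subject, shapes$predicate,
                            shapes$object), , drop = FALSE]
    rownames(shapes) <- NULL
  }
  attr(shapes, "turtle") <- writeTurtle(shapes)
  shapes
}

#' Validate RDF data against generated SHACL shapes
#'
#' A validator for the SHACL-core subset the shape generator emits:
#' class-targeted node shapes with `sh:path` / `sh:minCount` property
#' constraints. For every instance of each targeted class it checks
#' that each constrained path occurs at least `minCount` times.
#'
#' @param data_triples triple data.frame from [toRdf()].
#' @param shape_triples shape data.frame from [generateShacl()].
#' @return list(conforms = logical, violations = data.frame(focus,
#'   path, detail)).
#' @export
validateShacl <- function(data_triples, shape_triples) {
  iris <- rdfIris()
  sh <- shaclIris()
  viol <- list()
  shapes <- shape_triples$subject[
    shape_triples$predicate == iris$rdf_type &
      shape_triples$object == sh$node_shape]
  for (shape in unique(shapes)) {
    tclass <- shape_triples$object[
      shape_triples$subject == shape &
        shape_triples$predicate == sh$target_class]
    if (!length(tclass)) next
    pnodes <- shape_triples$object[
      shape_triples$subject == shape &
        shape_triples$predicate == sh$property]
    focus <- data_triples$subject[
      data_triples$predicate == iris$rdf_type &
        data_triples$object == tclass[1L]]
    for (pn in pnodes) {
      path <- shape_triples$object[
        shape_triples$subject == pn & shape_triples$predicate == sh$path]
      mc <- shape_triples$object[
        shape_triples$subject == pn &
          shape_triples$predicate == sh$min_count]
      mc <- if (length(mc)) as.integer(mc[1L]) else 0L
      if (mc < 1L || !length(path)) next
      for (f in focus) {
        n <- sum(data_triples$subject == f &
                   data_triples$predicate == path[1L])
        if (n < mc)
          viol[[length(viol) + 1L]] <- data.frame(
            focus = f, path = path[1L],
            detail = sprintf("minCount %d, found %d", mc, n),
            stringsAsFactors = FALSE)
      }
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(focus = character(), path = character(),
               detail = character(), stringsAsFactors = FALSE)
  list(conforms = !nrow(violations), violations = violations)
}

#' Triple-store repository manager
#'
#' A thin, transport-injectable wrapper around a GraphDB-style
#' repository HTTP API: create a repository, upload Turtle, run SPARQL.
#' All request payloads are deterministic and recorded on the handle so
#' tests (and audits) can replay them; no live server is ever contacted
#' unless the caller injects a real transport.
#'
#' @param endpoint list with at least `name` and `url`.
#' @param transport function(request) -> response; request is
#'   list(endpoint, action, path, body).
#' @return handle: list(create_repository, upload, sparql_query,
#'   requests) where requests() returns the recorded request list.
#' @export
triplestoreManager <- function(endpoint, transport) {
  stopifnot(is.list(endpoint), is.function(transport))
  log <- new.env(parent = emptyenv())
  log$requests <- list()
  send <- function(action, path, body) {
    req <- list(endpoint = endpoint$name %||% "unnamed", action = action,
                path = path, body = body)
    log$requests[[length(log$requests) + 1L]] <- req
    out <- tryCatch(transport(req), error = function(e) e)
    if (inherits(out, "error"))
      stopf("transport failure against endpoint '%s': %s",
            endpoint$name %||% "unnamed", conditionMessage(out),
            class = "ckg_transport_error")
    out
  }
  list(
    create_repository = function(repository_id) {
      send("create_repository",
           sprintf("/rest/repositories/%s", repository_id),
           sprintf('{"id": "%s"}', repository_id))
    },
    upload = function(turtle) {
      if (!nchar(turtle))
        stopf("refusing to upload an empty Turtle payload",
              class = "ckg_empty_payload_error")
      send("upload", "/statements", turtle)
    },
    sparql_query = function(query) {
      send("sparql_query", "/sparql", query)
    },
    requests = function() log$requests
  )
}
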