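# GraphML attribute keys are declared once, typed. Scalar attributes map
# to native GraphML attr.types; vector-valued or mixed attributes are
# JSON-encoded strings. The key id prefix encodes the decoding rule so
# import can reconstruct exact R types:
#   d = double, b = boolean, s = string, j = JSON   (n* node, e* edge)
graphmlType <- function(values) {
  scal <- all(vapply(values, function(v) length(v) == 1L && !is.na(v),
                     logical(1)))
  if (scal && all(vapply(values, is.numeric, logical(1)))) return("d")
  if (scal && all(vapply(values, is.logical, logical(1)))) return("b")
  if (scal && all(vapply(values, is.character, logical(1)))) return("s")
  "j"
}

graphmlAttrTypeName <- function(code) {
  switch(code, d = "double", b = "boolean", s = "string", j = "string")
}

encodeGraphmlValue <- function(v, code) {
  switch(code,
         d = sprintf("%.17g", v),
         b = if (v) "true" else "false",
         s = as.character(v),
         j = as.character(jsonlite::toJSON(v, digits = NA)))
}

decodeGraphmlValue <- function(txt, code) {
  switch(code,
         d = as.numeric(txt),
         b = identical(txt, "true"),
         s = txt,
         j = decodeJsonVector(txt))
}

decodeJsonVector <- function(txt) {
  v <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  v
}

collectAttrTypes <- function(attr_list) {
  names_all <- sortC(unique(unlist(lapply(attr_list, names))))
  types <- character()
  for (an in names_all) {
    vals <- Filter(Negate(is.null), lapply(attr_list, `[[`, an))
    types[[an]] <- graphmlType(vals)
  }
  types
}

#' Serialize a property graph to GraphML
#'
#' Writes a typed GraphML document (attribute keys declared once, with
#' attr.name and attr.type) suitable for loading into Neo4j via the
#' APOC importer. Node type, label, cross-references and provenance are
#' stored as declared attributes; [fromGraphml()] reconstructs the
#' original graph exactly, including numeric precision, vector-valued
#' attributes and per-edge provenance tables.
#'
#' @param graph a valid PropertyGraph.
#' @param path optional output file; when NULL the XML text is
#'   returned.
#' @return XML text (invisibly when written to file).
#' @export
toGraphml <- function(graph, path = NULL) {
  stopifnot(is(graph, "PropertyGraph"))
  nd <- graph@nodes[orderC(graph@nodes$key), , drop = FALSE]
  ed <- graph@edges
  if (nrow(ed))
    ed <- ed[orderC(ed$subject_key, ed$relation, ed$object_key), ,
             drop = FALSE]

  ntypes <- collectAttrTypes(nd$attributes)
  etypes <- collectAttrTypes(ed$attributes)

  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    x <- gsub("\"", "&quot;", x, fixed = TRUE)
    x
  }
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\" ",
           "xmlns:xsi=\"http://www.w3.org/2001/XMLSchema-instance\" ",
           "xsi:schemaLocation=\"http://graphml.graphdrawing.org/xmlns ",
           "http://graphml.graphdrawing.org/xmlns/1.0/graphml.xsd\">"))
  keydef <- function(id, domain, name, type)
    sprintf("  <key id=\"%s\" for=\"%s\" attr.name=\"%s\" attr.type=\"%s\"/>",
            id, domain, esc(name), type)
  lines <- c(lines,
             keydef("ns_node_type", "node", "node_type", "string"),
             keydef("ns_label", "node", "label", "string"),
             keydef("nj_xrefs", "node", "xrefs", "string"),
             keydef("es_relation", "edge", "relation", "string"),
             keydef("ej_provenance", "edge", "provenance", "string"))
  for (an in names(ntypes))
    lines <- c(lines, keydef(paste0("n", ntypes[[an]], "a_", an), "node",
                             an, graphmlAttrTypeName(ntypes[[an]])))
  for (an in names(etypes))
    lines <- c(lines, keydef(paste0("e", etypes[[an]], "a_", an), "edge",
                             an, graphmlAttrTypeName(etypes[[an]])))
  lines <- c(lines, "  <graph id=\"G\" edgedefault=\"directed\">")

  dataLine <- function(key, value)
    sprintf("      <data key=\"%s\">%s</data>", key, esc(value))

  for (i in seq_len(nrow(nd))) {
    lines <- c(lines, sprintf("    <node id=\"%s\">", esc(nd$key[i])),
               dataLine("ns_node_type", nd$node_type[i]),
               dataLine("ns_label", nd$label[i]))
    xr <- nd$xrefs[[i]]
    if (length(xr))
      lines <- c(lines, dataLine("nj_xrefs",
        as.character(jsonlite::toJSON(
          list(ns = names(xr), acc = unname(xr))))))
    a <- nd$attributes[[i]]
    for (an in names(a)) {
      code <- ntypes[[an]]
      lines <- c(lines, dataLine(paste0("n", code, "a_", an),
                                 encodeGraphmlValue(a[[an]], code)))
    }
    lines <- c(lines, "    </node>")
  }
  for (i in seq_len(nrow(ed))) {
    lines <- c(lines,
               sprintf("    <edge id=\"e%d\" source=\"%s\" target=\"%s\">",
                       i, esc(ed$subject_key[i]), esc(ed$object_key[i])),
               dataLine("es_relation", ed$relation[i]))
    p <- ed$provenance[[i]]
    lines <- c(lines, dataLine("ej_provenance",
      as.character(jsonlite::toJSON(
        list(source_name = p$source_name,
             source_version = p$source_version,
             retrieval_date = p$retrieval_date)))))
    a <- ed$attributes[[i]]
    for (an in names(a)) {
      code <- etypes[[an]]
      lines <- c(lines, dataLine(paste0("e", code, "a_", an),
                                 encodeGraphmlValue(a[[an]], code)))
    }
    lines <- c(lines, "    </edge>")
  }
  lines <- c(lines, "  </graph>", "</graphml>")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

#' Import a GraphML document written by [toGraphml()]
#'
#' @param x XML text or a file path.
#' @return a PropertyGraph. Data elements referring to an undeclared
#'   attribute key raise a format error naming the element.
#' @export
fromGraphml <- function(x) {
  doc <- if (is.character(x) && length(x) == 1L && file.exists(x))
    xml2::read_xml(x) else xml2::read_xml(paste(x, collapse = "\n"))
  xml2::xml_ns_strip(doc)

  keys <- xml2::xml_find_all(doc, "./key")
  keymap <- list()
  for (k in keys) {
    id <- xml2::xml_attr(k, "id")
    keymap[[id]] <- list(name = xml2::xml_attr(k, "attr.name"),
                         domain = xml2::xml_attr(k, "for"))
  }
  readData <- function(el, el_id) {
    out <- list()
    for (d in xml2::xml_find_all(el, "./data")) {
      kid <- xml2::xml_attr(d, "key")
      if (is.null(keymap[[kid]]))
        stopf("undeclared attribute key '%s' on element '%s'", kid, el_id,
              class = "ckg_format_error")
      out[[kid]] <- xml2::xml_text(d)
    }
    out
  }
  decodeAttrs <- function(data, prefix) {
    ids <- grep(paste0("^", prefix, "[dbsj]a_"), names(data), value = TRUE)
    out <- structure(list(), names = character())
    for (id in ids) {
      code <- substr(id, 2L, 2L)
      an <- sub(paste0("^", prefix, "[dbsj]a_"), "", id)
      out[[an]] <- decodeGraphmlValue(data[[id]], code)
    }
    out[sortC(names(out))]
  }

  nxml <- xml2::xml_find_all(doc, "./graph/node")
  nd <- emptyNodeTable()
  if (length(nxml)) {
    recs <- lapply(nxml, function(n) {
      id <- xml2::xml_attr(n, "id")
      data <- readData(n, id)
      xr <- character()
      if (!is.null(data$nj_xrefs)) {
        o <- jsonlite::fromJSON(data$nj_xrefs, simplifyVector = TRUE)
        xr <- stats::setNames(as.character(o$acc), as.character(o$ns))
      }
      list(key = id, node_type = data$ns_node_type, label = data$ns_label,
           xrefs = xr, attributes = decodeAttrs(data, "n"))
    })
    nd <- data.frame(key = vapply(recs, `[[`, character(1), "key"),
                     node_type = vapply(recs, `[[`, character(1), "node_type"),
                     label = vapply(recs, `[[`, character(1), "label"),
                     stringsAsFactors = FALSE)
    nd$xrefs <- lapply(recs, `[[`, "xrefs")
    nd$attributes <- lapply(recs, `[[`, "attributes")
    ord <- orderC(nd$key)
    nd <- nd[ord, , drop = FALSE]
    rownames(nd) <- NULL
  }

  exml <- xml2::xml_find_all(doc, "./graph/edge")
  ed <- emptyEdgeTable()
  if (length(exml)) {
    recs <- lapply(exml, function(e) {
      id <- xml2::xml_attr(e, "id")
      data <- readData(e, id)
      p <- emptyProvenance()
      if (!is.null(data$ej_provenance)) {
        o <- jsonlite::fromJSON(data$ej_provenance, simplifyVector = TRUE)
        p <- data.frame(source_name = as.character(o$source_name),
                        source_version = as.character(o$source_version),
                        retrieval_date = as.character(o$retrieval_date),
                        stringsAsFactors = FALSE)
      }
      list(subject_key = xml2::xml_attr(e, "source"),
           relation = data$es_relation,
           object_key = xml2::xml_attr(e, "target"),
           provenance = p, attributes = decodeAttrs(data, "e"))
    })
    ed <- data.frame(
      subject_key = vapply(recs, `[[`, character(1), "subject_key"),
      relation = vapply(recs, `[[`, character(1), "relation"),
      object_key = vapply(recs, `[[`, character(1), "object_key"),
      stringsAsFactors = FALSE)
    ed$provenance <- lapply(recs, `[[`, "provenance")
    ed$attributes <- lapply(recs, `[[`, "attributes")
    ord <- orderC(ed$subject_key, ed$relation, ed$object_key)
    ed <- ed[ord, , drop = FALSE]
    rownames(ed) <- NULL
  }
  new("PropertyGraph", nodes = nd, edges = ed,
      metadata = list(query_metadata = NULL,
                      harmonization = "imported from GraphML"))
}
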