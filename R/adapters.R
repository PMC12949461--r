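# namespace each concrete source expects its gene accessions in; canonical
# gene keys are Entrez, so translation goes through HarmonizedTable xrefs
sourceNamespaces <- function() {
  c(DisGeNET = "ENTREZ", OpenTargets = "ENSEMBL", MINERVA = "HGNC",
    STRING = "STRING", Bgee = "ENSEMBL")
}

emptyAnnotationRows <- function() {
  d <- data.frame(subject_key = character(), relation = character(),
                  object_key = character(), object_type = character(),
                  object_label = character(), subject_type = character(),
                  subject_label = character(), metadata_ref = character(),
                  stringsAsFactors = FALSE)
  d$object_attributes <- list()
  d$edge_attributes <- list()
  d[, annotationRowColumns()]
}

annotationRowColumns <- function() {
  c("subject_key", "relation", "object_key", "object_type",
    "object_label", "subject_type", "subject_label",
    "object_attributes", "edge_attributes", "metadata_ref")
}

# subject_type/subject_label are only set when the subject is not an
# input entity (e.g. a drug acting on an input gene), so the graph
# builder can create the node
makeAnnotationRow <- function(subject_key, relation, object_key,
                              object_type, object_label,
                              object_attributes = list(),
                              edge_attributes = list(),
                              subject_type = NA_character_,
                              subject_label = NA_character_,
                              metadata_ref = NA_character_) {
  assertRelation(relation)
  assertNodeType(object_type)
  if (!is.na(subject_type)) assertNodeType(subject_type)
  d <- data.frame(subject_key = subject_key, relation = relation,
                  object_key = object_key, object_type = object_type,
                  object_label = object_label,
                  subject_type = subject_type,
                  subject_label = subject_label,
                  metadata_ref = metadata_ref, stringsAsFactors = FALSE)
  d$object_attributes <- list(object_attributes)
  d$edge_attributes <- list(edge_attributes)
  d[, annotationRowColumns()]
}

bindAnnotationRows <- function(rows) {
  if (!length(rows)) return(emptyAnnotationRows())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# translate canonical keys into the namespace a source expects.
# Returns list(keys, accessions, skipped).
translateBatch <- function(source_name, batch, xrefs = NULL) {
  ns <- sourceNamespaces()[[source_name]]
  keys <- character()
  acc <- character()
  skipped <- character()
  for (k in batch) {
    cur <- splitCurie(k)
    if (!is.na(cur$namespace) && cur$namespace == ns) {
      keys <- c(keys, k)
      acc <- c(acc, cur$accession)
      next
    }
    xr <- xrefs[[k]]
    hit <- unname(xr[names(xr) == ns])
    if (length(hit)) {
      keys <- c(keys, k)
      acc <- c(acc, sortC(hit)[1L])
    } else {
      skipped <- c(skipped, k)
    }
  }
  list(keys = keys, accessions = acc, skipped = skipped)
}

#' Build a source-specific request for a batch of entities
#'
#' Translates canonical keys into the namespace the source expects
#' (through the harmonized cross-references) and renders the query in
#' the source's dialect: REST URL query strings for DisGeNET, MINERVA
#' and STRING, a GraphQL document for OpenTargets, a SPARQL query for
#' Bgee. Building is deterministic: the same batch yields a byte
#' identical payload with accessions in input order. Keys lacking a
#' cross-reference in the required namespace are skipped, not fatal.
#'
#' @param source_name one of the five concrete sources.
#' @param batch character vector of canonical keys (non-empty).
#' @param xrefs named list, canonical key -> named character vector of
#'   cross-references (as stored in a HarmonizedTable).
#' @param catalog source catalog, by default [defaultCatalog()].
#' @return list of class `"ckgSourceRequest"`: source_name, dialect,
#'   payload, entity_batch (canonical keys actually queried), translated
#'   (their accessions), skipped (keys without translation).
#' @export
buildRequest <- function(source_name, batch, xrefs = NULL,
                         catalog = defaultCatalog()) {
  entry <- catalogEntry(catalog, source_name)
  if (!entry$concrete)
    stopf("source '%s' has no concrete adapter", source_name,
          class = "ckg_unsupported_source_error")
  if (!length(batch))
    stopf("empty entity batch for source '%s'", source_name,
          class = "ckg_precondition_error")
  tr <- translateBatch(source_name, batch, xrefs)
  payload <- switch(source_name,
    "DisGeNET" = paste0("https://api.disgenet.example/api/v1/gda/summary",
                        "?gene_ncbi_id=",
                        paste(tr$accessions, collapse = ",")),
    "MINERVA" = paste0("https://minerva.example/api/projects/context/",
                       "bioEntities:search?query=",
                       paste(tr$accessions, collapse = ",")),
    "STRING" = paste0("https://string.example/api/json/network",
                      "?identifiers=",
                      paste(tr$accessions, collapse = "%0d"),
                      "&species=9606"),
    "OpenTargets" = opentargetsQuery(tr$accessions),
    "Bgee" = bgeeQuery(tr$accessions))
  structure(list(source_name = source_name,
                 dialect = entry$query_dialect,
                 payload = payload,
                 entity_batch = tr$keys,
                 translated = tr$accessions,
                 skipped = tr$skipped),
            class = "ckgSourceRequest")
}

opentargetsQuery <- function(accessions) {
  ids <- paste(sprintf('"%s"', accessions), collapse = ", ")
  paste0(
    "query annotateTargets {\n",
    "  targets(ensemblIds: [", ids, "]) {\n",
    "    id\n",
    "    associatedDiseases { rows { disease { id name dbXRefs } score } }\n",
    "    knownDrugs { rows { drug { id name crossReferences { source reference } }",
    " mechanismOfAction disease { id name dbXRefs } } }\n",
    "    pathways { pathwayId pathway }\n",
    "  }\n",
    "}\n")
}

bgeeQuery <- function(accessions) {
  vals <- paste(sprintf('"%s"', accessions), collapse = " ")
  paste0(
    "PREFIX genex: <http://purl.org/genex#>\n",
    "PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>\n",
    "SELECT ?gene ?anat ?anatName ?level ?stage ?over WHERE {\n",
    "  VALUES ?gene { ", vals, " }\n",
    "  ?expr genex:hasSequenceUnit ?gene ;\n",
    "        genex:hasAnatomicalEntity ?anat ;\n",
    "        genex:hasExpressionLevel ?level ;\n",
    "        genex:hasDevelopmentalStage ?stage ;\n",
    "        genex:isOverExpressed ?over .\n",
    "  ?anat rdfs:label ?anatName .\n",
    "}\n")
}

parseJsonBody <- function(source_name, body) {
  out <- tryCatch(jsonlite::fromJSON(body, simplifyVector = FALSE),
                  error = function(e) e)
  if (inherits(out, "error"))
    stopf("schema drift in %s response: body is not parseable JSON (%s)",
          source_name, conditionMessage(out),
          class = "ckg_schema_drift_error")
  out
}

needField <- function(x, path, source_name) {
  cur <- x
  for (p in path) {
    if (!is.list(cur) || is.null(cur[[p]]))
      stopf("schema drift in %s response: missing field '%s'",
            source_name, paste(path, collapse = "."),
            class = "ckg_schema_drift_error")
    cur <- cur[[p]]
  }
  cur
}

# reverse map: accession in source namespace -> canonical key
reverseTranslation <- function(source_name, batch, xrefs) {
  tr <- translateBatch(source_name, batch, xrefs)
  as.list(stats::setNames(tr$keys, tr$accessions))
}

#' Parse a source response into annotation rows
#'
#' Every emitted row's subject is a member of the queried batch (foreign
#' subjects are dropped); object identifiers are re-expressed as
#' canonical keys (UMLS for diseases, PubChem CIDs for compounds where a
#' cross-reference is present, otherwise the source's own namespace).
#' Source-specific evidence lands in edge attributes: association score
#' for DisGeNET-shaped responses, interaction score for STRING-shaped,
#' expression level / developmental stage / over-expression flag for
#' Bgee-shaped.
#'
#' @param source_name one of the five concrete sources.
#' @param response list(source_name, body, status) as returned by a
#'   transport.
#' @param batch canonical keys that were queried.
#' @param xrefs cross-reference list as in [buildRequest()].
#' @return data.frame of annotation rows (possibly empty).
#' @export
parseResponse <- function(source_name, response, batch, xrefs = NULL) {
  if (!is.null(response$status) && response$status >= 400L)
    stopf("source %s returned HTTP status %d", source_name,
          response$status, class = "ckg_transport_error")
  back <- reverseTranslation(source_name, batch, xrefs)
  body <- parseJsonBody(source_name, response$body)
  rows <- switch(source_name,
    "DisGeNET" = parseDisgenet(body, back),
    "OpenTargets" = parseOpentargets(body, back),
    "MINERVA" = parseMinerva(body, back),
    "STRING" = parseString(body, back),
    "Bgee" = parseBgee(body, back),
    stopf("source '%s' has no concrete adapter", source_name,
          class = "ckg_unsupported_source_error"))
  rows
}

parseDisgenet <- function(body, back) {
  recs <- needField(body, "payload", "DisGeNET")
  out <- list()
  for (r in recs) {
    gid <- as.character(needField(r, "geneid", "DisGeNET"))
    subj <- back[[gid]]
    if (is.null(subj)) next
    umls <- needField(r, "disease_umls", "DisGeNET")
    out[[length(out) + 1L]] <- makeAnnotationRow(
      subject_key = subj, relation = "associated_with",
      object_key = canonicalKey("UMLS", umls),
      object_type = "disease",
      object_label = r$disease_name %||% umls,
      edge_attributes = list(disgenet_score = as.numeric(r$score %||% NA_real_)))
  }
  bindAnnotationRows(out)
}

opentargetsDiseaseKey <- function(disease) {
  xr <- unlist(disease$dbXRefs %||% list())
  umls <- grep("^UMLS:", xr, value = TRUE)
  if (length(umls)) return(umls[1L])
  canonicalKey("EFO", disease$id)
}

parseOpentargets <- function(body, back) {
  targets <- needField(body, c("data", "targets"), "OpenTargets")
  out <- list()
  for (t in targets) {
    subj <- back[[as.character(needField(t, "id", "OpenTargets"))]]
    if (is.null(subj)) next
    for (r in (t$associatedDiseases$rows %||% list())) {
      dis <- needField(r, "disease", "OpenTargets")
      out[[length(out) + 1L]] <- makeAnnotationRow(
        subject_key = subj, relation = "associated_with",
        object_key = opentargetsDiseaseKey(dis),
        object_type = "disease", object_label = dis$name %||% dis$id,
        edge_attributes = list(opentargets_score = as.numeric(r$score %||% NA_real_)))
    }
    for (r in (t$knownDrugs$rows %||% list())) {
      drug <- needField(r, "drug", "OpenTargets")
      cid <- NULL
      for (cr in (drug$crossReferences %||% list()))
        if (identical(cr$source, "PubChem")) cid <- cr$reference
      drug_key <- if (!is.null(cid)) canonicalKey("PUBCHEM", cid)
                  else canonicalKey("CHEMBL", drug$id)
      moa <- r$mechanismOfAction %||% "unknown"
      relation <- if (grepl("activat|agonist", moa, ignore.case = TRUE))
        "activates" else "inhibits"
      drug_label <- drug$name %||% drug$id
      out[[length(out) + 1L]] <- makeAnnotationRow(
        subject_key = drug_key, relation = relation, object_key = subj,
        object_type = "gene", object_label = subj,
        subject_type = "compound", subject_label = drug_label,
        edge_attributes = list(mechanism_of_action = moa))
      if (!is.null(r$disease)) {
        out[[length(out) + 1L]] <- makeAnnotationRow(
          subject_key = drug_key, relation = "treats",
          object_key = opentargetsDiseaseKey(r$disease),
          object_type = "disease",
          object_label = r$disease$name %||% r$disease$id,
          subject_type = "compound", subject_label = drug_label)
      }
    }
    for (p in (t$pathways %||% list())) {
      out[[length(out) + 1L]] <- makeAnnotationRow(
        subject_key = subj, relation = "part_of",
        object_key = canonicalKey("WIKIPATHWAYS",
                                  needField(p, "pathwayId", "OpenTargets")),
        object_type = "pathway", object_label = p$pathway %||% p$pathwayId)
    }
  }
  bindAnnotationRows(out)
}

parseMinerva <- function(body, back) {
  out <- list()
  for (r in body) {
    subj <- back[[as.character(needField(r, "gene", "MINERVA"))]]
    if (is.null(subj)) next
    for (p in (r$pathways %||% list())) {
      out[[length(out) + 1L]] <- makeAnnotationRow(
        subject_key = subj, relation = "part_of",
        object_key = canonicalKey("MINERVA",
                                  needField(p, "id", "MINERVA")),
        object_type = "pathway", object_label = p$name %||% p$id)
    }
  }
  bindAnnotationRows(out)
}

parseString <- function(body, back) {
  out <- list()
  for (r in body) {
    a <- back[[as.character(needField(r, "stringId_A", "STRING"))]]
    b_acc <- as.character(needField(r, "stringId_B", "STRING"))
    b <- back[[b_acc]]
    if (is.null(a)) next
    obj_key <- if (!is.null(b)) b else canonicalKey("STRING", b_acc)
    obj_label <- r$preferredName_B %||% obj_key
    out[[length(out) + 1L]] <- makeAnnotationRow(
      subject_key = a, relation = "interacts_with", object_key = obj_key,
      object_type = "gene", object_label = obj_label,
      edge_attributes = list(string_score = as.numeric(r$score %||% NA_real_)))
  }
  bindAnnotationRows(out)
}

parseBgee <- function(body, back) {
  bindings <- needField(body, c("results", "bindings"), "Bgee")
  out <- list()
  for (b in bindings) {
    subj <- back[[as.character(needField(b, c("gene", "value"), "Bgee"))]]
    if (is.null(subj)) next
    anat_iri <- needField(b, c("anat", "value"), "Bgee")
    uberon <- sub("^.*/", "", anat_iri)
    uberon_key <- canonicalKey("UBERON", sub("^UBERON_", "", uberon))
    out[[length(out) + 1L]] <- makeAnnotationRow(
      subject_key = subj, relation = "expressed_by",
      object_key = uberon_key, object_type = "anatomical_entity",
      object_label = b$anatName$value %||% uberon,
      edge_attributes = list(
        expression_level = as.numeric(b$level$value %||% NA_real_),
        developmental_stage = b$stage$value %||% "unknown",
        over_expressed = identical(b$over$value, "true")))
  }
  bindAnnotationRows(out)
}

goldenBatches <- function() {
  list(
    "DisGeNET" = list(batch = c("ENTREZ:7157", "ENTREZ:3569"),
                      xrefs = NULL),
    "OpenTargets" = list(
      batch = "ENTREZ:7157",
      xrefs = list("ENTREZ:7157" = c(ENSEMBL = "ENSG00000141510"))),
    "MINERVA" = list(
      batch = "ENTREZ:7157",
      xrefs = list("ENTREZ:7157" = c(HGNC = "TP53"))),
    "STRING" = list(
      batch = c("ENTREZ:7157", "ENTREZ:3569"),
      xrefs = list("ENTREZ:7157" = c(STRING = "9606.ENSP00000269305"),
                   "ENTREZ:3569" = c(STRING = "9606.ENSP00000258743"))),
    "Bgee" = list(
      batch = "ENTREZ:7157",
      xrefs = list("ENTREZ:7157" = c(ENSEMBL = "ENSG00000141510")))
  )
}

#' Run an adapter against its bundled golden fixture
#'
#' Rebuilds the request for the frozen batch, replays the recorded
#' response body, and compares payload and parsed rows field by field
#' against the stored expectations under
#' `inst/extdata/fixtures/<source>/`. Differences are report content,
#' never errors, so scheduled runs can diff against upstream drift.
#'
#' @param source_name a concrete source.
#' @param fixtures_dir directory holding the fixtures (defaults to the
#'   installed copies).
#' @return list(source, pass, diffs) where diffs is a character vector
#'   of field-level differences.
#' @export
adapterSelftest <- function(source_name,
                            fixtures_dir = system.file("extdata", "fixtures",
                                                       package = "ContextKG")) {
  gb <- goldenBatches()[[source_name]]
  if (is.null(gb))
    stopf("source '%s' has no concrete adapter", source_name,
          class = "ckg_unsupported_source_error")
  dir <- file.path(fixtures_dir, gsub("[^A-Za-z0-9]", "_", source_name))
  req_file <- file.path(dir, "request.txt")
  body_file <- file.path(dir, "response.body")
  exp_file <- file.path(dir, "expected_rows.tsv")
  diffs <- character()

  req <- buildRequest(source_name, gb$batch, gb$xrefs)
  expected_payload <- paste(readLines(req_file, warn = FALSE),
                            collapse = "\n")
  if (!identical(trimws2(req$payload), trimws2(expected_payload)))
    diffs <- c(diffs, "payload: built request differs from recorded request")

  body <- paste(readLines(body_file, warn = FALSE), collapse = "\n")
  rows <- tryCatch(
    parseResponse(source_name,
                  list(source_name = source_name, body = body,
                       status = 200L),
                  gb$batch, gb$xrefs),
    error = function(e) e)
  if (inherits(rows, "error")) {
    diffs <- c(diffs, paste0("parse: ", conditionMessage(rows)))
  } else {
    expd <- utils::read.table(exp_file, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE, quote = "\"")
    cols <- c("subject_key", "relation", "object_key", "object_type",
              "object_label")
    got <- rows[, cols, drop = FALSE]
    got <- got[do.call(orderC, got), , drop = FALSE]
    expd <- expd[do.call(orderC, expd[cols]), cols, drop = FALSE]
    rownames(got) <- rownames(expd) <- NULL
    if (nrow(got) != nrow(expd)) {
      diffs <- c(diffs, sprintf("rows: expected %d, got %d",
                                nrow(expd), nrow(got)))
    } else {
      for (cn in cols) {
        bad <- which(got[[cn]] != expd[[cn]])
        if (length(bad))
          diffs <- c(diffs, sprintf("field %s: mismatch at row(s) %s",
                                    cn, paste(bad, collapse = ",")))
      }
    }
  }
  list(source = source_name, pass = !length(diffs), diffs = diffs)
}
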