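#' The registry of queryable data sources
#'
#' Returns the 15 shipped data-source descriptors with their query
#' dialects (SPARQL endpoints, REST APIs, GraphQL, or plain tabular FILE
#' downloads), the entity kinds they accept, and the typed edge
#' categories each can contribute to the graph. Five sources (DisGeNET,
#' OpenTargets, MINERVA, STRING, Bgee) ship with concrete request
#' builders and response parsers; the rest are catalog-registered stubs
#' that satisfy the same contract but have no parser yet.
#'
#' Edge categories are (subject node type, relation, object node type)
#' triples. The four-source selection DisGeNET + OpenTargets + MINERVA +
#' STRING collapses to exactly five node-type pair categories
#' (gene-disease, gene-compound, disease-compound, gene-pathway,
#' gene-gene); Gene Ontology part_of categories live under g:Profiler.
#'
#' @return data.frame with columns name, query_dialect, concrete, and
#'   list-columns supported_entities and edge_categories (each category a
#'   character vector c(subject, relation, object)).
#' @export
#' @examples
#' cat15 <- defaultCatalog()
#' nrow(cat15)
defaultCatalog <- function() {
  d <- function(subject, relation, object) c(subject, relation, object)
  entries <- list(
    list(name = "AOP WIKI RDF", dialect = "SPARQL", concrete = FALSE,
         entities = c("gene", "compound", "key_event"),
         cats = list(d("gene", "associated_with", "key_event"),
                     d("molecular_initiating_event", "upstream_of", "key_event"),
                     d("key_event", "upstream_of", "adverse_outcome"),
                     d("key_event", "part_of", "adverse_outcome_pathway"),
                     d("gene", "part_of", "biological_process"))),
    list(name = "Bgee", dialect = "SPARQL", concrete = TRUE,
         entities = c("gene", "anatomical_entity"),
         cats = list(d("gene", "expressed_by", "anatomical_entity"))),
    list(name = "DisGeNET", dialect = "API", concrete = TRUE,
         entities = c("gene", "disease"),
         cats = list(d("gene", "associated_with", "disease"))),
    list(name = "g:Profiler", dialect = "API", concrete = FALSE,
         entities = c("gene", "pathway"),
         cats = list(d("gene", "part_of", "pathway"),
                     d("gene", "part_of", "biological_process"),
                     d("gene", "part_of", "molecular_function"),
                     d("gene", "part_of", "cellular_component"))),
    list(name = "IntAct", dialect = "API", concrete = FALSE,
         entities = c("gene", "compound"),
         cats = list(d("gene", "interacts_with", "gene"),
                     d("compound", "interacts_with", "gene"))),
    list(name = "KEGG", dialect = "API", concrete = FALSE,
         entities = c("compound", "gene", "pathway"),
         cats = list(d("gene", "part_of", "pathway"),
                     d("compound", "part_of", "pathway"))),
    list(name = "MINERVA", dialect = "API", concrete = TRUE,
         entities = c("compound", "gene", "pathway"),
         cats = list(d("gene", "part_of", "pathway"))),
    list(name = "MitoCarta", dialect = "FILE", concrete = FALSE,
         entities = c("gene", "mitochondrial_pathway"),
         cats = list(d("gene", "part_of", "mitochondrial_pathway"))),
    list(name = "MolMeDB", dialect = "SPARQL", concrete = FALSE,
         entities = c("compound", "gene"),
         cats = list(d("compound", "inhibits", "gene"))),
    list(name = "OpenTargets", dialect = "GraphQL", concrete = TRUE,
         entities = c("compound", "gene", "pathway", "disease"),
         cats = list(d("gene", "associated_with", "disease"),
                     d("compound", "activates", "gene"),
                     d("compound", "inhibits", "gene"),
                     d("compound", "treats", "disease"),
                     d("gene", "part_of", "pathway"))),
    list(name = "PubChem", dialect = "SPARQL", concrete = FALSE,
         entities = c("compound", "gene"),
         cats = list(d("compound", "associated_with", "gene"))),
    list(name = "STRING", dialect = "API", concrete = TRUE,
         entities = c("gene"),
         cats = list(d("gene", "interacts_with", "gene"))),
    list(name = "TFLink", dialect = "FILE", concrete = FALSE,
         entities = c("transcription_factor", "gene"),
         cats = list(d("transcription_factor", "activates", "gene"),
                     d("transcription_factor", "inhibits", "gene"))),
    list(name = "Wikidata", dialect = "SPARQL", concrete = FALSE,
         entities = c("gene"),
         cats = list(d("gene", "associated_with", "disease"))),
    list(name = "WikiPathways", dialect = "SPARQL", concrete = FALSE,
         entities = c("gene", "pathway"),
         cats = list(d("gene", "part_of", "pathway")))
  )
  out <- data.frame(
    name = vapply(entries, `[[`, character(1), "name"),
    query_dialect = vapply(entries, `[[`, character(1), "dialect"),
    concrete = vapply(entries, `[[`, logical(1), "concrete"),
    stringsAsFactors = FALSE)
  out$supported_entities <- lapply(entries, `[[`, "entities")
  out$edge_categories <- lapply(entries, `[[`, "cats")
  # catalog closure: every category drawn from the closed vocabularies
  for (cats in out$edge_categories) {
    for (cc in cats) {
      assertNodeType(cc[c(1L, 3L)])
      assertRelation(cc[2L])
    }
  }
  out
}

catalogEntry <- function(catalog, name) {
  i <- match(name, catalog$name)
  if (is.na(i))
    stopf("unknown data source '%s'", name, class = "ckg_lookup_error")
  catalog[i, , drop = FALSE]
}

#' Edge categories contributed by a set of sources
#'
#' @param catalog catalog data.frame, typically [defaultCatalog()].
#' @param selected character vector of source names (subset of the
#'   catalog).
#' @return data.frame with columns subject_type, relation, object_type;
#'   one row per distinct category.
#' @export
#' @examples
#' edgeCategoriesFor(defaultCatalog(),
#'                   c("DisGeNET", "OpenTargets", "MINERVA", "STRING"))
edgeCategoriesFor <- function(catalog, selected) {
  unknown <- setdiff(selected, catalog$name)
  if (length(unknown))
    stopf("unknown data source(s): %s", paste(unknown, collapse = ", "),
          class = "ckg_lookup_error")
  cats <- list()
  for (nm in selected) {
    e <- catalogEntry(catalog, nm)
    cats <- c(cats, e$edge_categories[[1L]])
  }
  out <- data.frame(subject_type = character(), relation = character(),
                    object_type = character(), stringsAsFactors = FALSE)
  if (length(cats)) {
    m <- do.call(rbind, cats)
    out <- data.frame(subject_type = m[, 1L], relation = m[, 2L],
                      object_type = m[, 3L], stringsAsFactors = FALSE)
    out <- unique(out)
    out <- out[orderC(out$subject_type, out$relation, out$object_type), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Collapse edge categories to unordered node-type pairs
#'
#' Used to compare a source selection against the coarse edge-type view
#' (e.g. "gene-disease, gene-compound, ...").
#'
#' @param categories data.frame from [edgeCategoriesFor()].
#' @return character vector of unique "a-b" pairs, each pair sorted
#'   alphabetically, except self-pairs which stay "a-a".
#' @export
collapseToNodePairs <- function(categories) {
  if (!nrow(categories)) return(character())
  pairs <- mapply(function(a, b) paste(sortC(c(a, b)), collapse = "-"),
                  categories$subject_type, categories$object_type)
  sortC(unique(unname(pairs)))
}

#' Export the catalog as stable-order JSON
#'
#' @param catalog catalog data.frame.
#' @param path optional file path; when NULL the JSON text is returned.
#' @return JSON text (invisibly when written to a file).
#' @export
catalogToJson <- function(catalog, path = NULL) {
  items <- lapply(seq_len(nrow(catalog)), function(i) {
    list(name = catalog$name[i],
         query_dialect = catalog$query_dialect[i],
         concrete = catalog$concrete[i],
         supported_entities = catalog$supported_entities[[i]],
         edge_categories = lapply(catalog$edge_categories[[i]], as.list))
  })
  txt <- jsonlite::toJSON(items, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}
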