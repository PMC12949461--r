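#' Read a pipeline run configuration
#'
#' YAML file mirroring the arguments of [runPipeline()]; see the
#' package vignette for the full schema.
#'
#' @param path YAML file path.
#' @return config list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path))
    stopf("config file '%s' does not exist", path,
          class = "ckg_config_error")
  yaml::read_yaml(path)
}

defaultRunConfig <- function() {
  list(input = NULL, input_kind = "gene_list", column_map = NULL,
       mapping = NULL, sources = character(), fetcher = "fixture",
       seed = 1L, density = 0.5, batch_size = 25L,
       context_nodes = list(), formats = exportFormats(),
       output_dir = ".", base_iri = "https://contextkg.example/kg",
       hub_namespace = "HGNC")
}

#' Run the end-to-end knowledge-graph pipeline
#'
#' Executes the four stages in order — harmonize, annotate, build,
#' analyze/serialize — writing the requested export formats, the graph
#' summary, the unmapped-identifier and per-source failure reports, and
#' a JSON run report embedding the full query-metadata list. Per-source
#' transport failures never abort the run; they surface in the failure
#' report.
#'
#' @param config list (see [readRunConfig()]) with elements: `input`
#'   (path / vector / data.frame), `input_kind`, optional `column_map`,
#'   `mapping` (mapping TSV path or data.frame), `sources` (character),
#'   `fetcher` ("fixture" or a transport function), `seed`, `density`,
#'   `batch_size`, `context_nodes` (list of
#'   list(key, node_type, label, links = list(list(entity_key,
#'   relation)), provenance_tag)), `formats`, `output_dir`, `base_iri`.
#' @return run report list (artifact paths, summary, query metadata,
#'   failures), invisibly; also written to `report.json`.
#' @export
runPipeline <- function(config) {
  cfg <- defaultRunConfig()
  for (nm in names(config)) cfg[[nm]] <- config[[nm]]
  if (is.null(cfg$input))
    stopf("config lacks 'input'", class = "ckg_config_error")
  bad_fmt <- setdiff(cfg$formats, exportFormats())
  if (length(bad_fmt))
    stopf("unknown export format(s): %s", paste(bad_fmt, collapse = ", "),
          class = "ckg_config_error")
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$output_dir, f)
  stage <- function(msg) message(sprintf("[contextkg] %s", msg))

  stage("stage 1/4: harmonize")
  records <- parseInput(cfg$input, cfg$input_kind,
                        cfg$column_map %||%
                          list(identifier = "identifier",
                               effect = "log2fc",
                               significance = "p_value"))
  mappings <- if (is.null(cfg$mapping)) emptyMappings()
              else if (is.data.frame(cfg$mapping)) cfg$mapping
              else loadMappingTable(cfg$mapping)
  table <- mapIdentifiers(records, mappings,
                          hub_namespace = cfg$hub_namespace)
  writeUnmappedReport(table, out("unmapped.tsv"))

  stage("stage 2/4: annotate")
  fetcher <- cfg$fetcher
  if (identical(fetcher, "fixture"))
    fetcher <- fixtureFetcher(cfg$seed, cfg$density)
  ann <- annotateTable(table, cfg$sources, fetcher,
                       batch_size = cfg$batch_size)
  writeFailureReport(ann$failures, out("failures.jsonl"))

  stage("stage 3/4: build graph")
  graph <- buildGraph(table, ann$rows, ann$metadata)
  for (cn in cfg$context_nodes) {
    links <- NULL
    if (length(cn$links)) {
      links <- data.frame(
        entity_key = vapply(cn$links, `[[`, character(1), "entity_key"),
        relation = vapply(cn$links, `[[`, character(1), "relation"),
        stringsAsFactors = FALSE)
      links <- links[links$entity_key %in% graph@nodes$key, , drop = FALSE]
    }
    graph <- addContextNode(graph, cn$key, cn$node_type, cn$label,
                            links = links,
                            provenance_tag = cn$provenance_tag %||% "curated",
                            provenance_date = cn$provenance_date %||%
                              "unknown")
  }
  violations <- validateGraph(graph)
  if (nrow(violations))
    stopf("built graph violates invariants: %s",
          paste(violations$rule, violations$detail, collapse = "; "),
          class = "ckg_integrity_error")

  stage("stage 4/4: analyze and serialize")
  artifacts <- list(unmapped = out("unmapped.tsv"),
                    failures = out("failures.jsonl"))
  if ("cytoscape" %in% cfg$formats) {
    toCytoscapeJson(graph, out("graph.cyjs"))
    artifacts$cytoscape <- out("graph.cyjs")
  }
  if ("graphml" %in% cfg$formats) {
    toGraphml(graph, out("graph.graphml"))
    artifacts$graphml <- out("graph.graphml")
  }
  if ("rdf" %in% cfg$formats) {
    policy <- uriPolicy(cfg$base_iri)
    triples <- toRdf(graph, policy = policy)
    writeTurtle(triples, out("graph.ttl"))
    shapes <- generateShacl(graph, policy = policy)
    writeTurtle(shapes, out("graph.shacl.ttl"))
    artifacts$rdf <- out("graph.ttl")
    artifacts$shacl <- out("graph.shacl.ttl")
  }
  summary <- summarizeGraph(graph)
  writeSummary(summary, out("summary.json"))
  artifacts$summary <- out("summary.json")

  report <- list(
    artifacts = artifacts,
    summary = summaryToList(summary),
    mapped_entities = nrow(harmonizedRows(table)),
    unmapped_entities = nrow(unmappedRecords(table)),
    query_metadata = ann$metadata,
    failures = ann$failures)
  writeLines(as.character(jsonlite::toJSON(report, auto_unbox = TRUE,
                                           digits = NA, pretty = TRUE,
                                           dataframe = "rows")),
             out("report.json"), useBytes = TRUE)
  report$graph <- graph
  report$table <- table
  invisible(report)
}
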