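emptyQueryMetadata <- function() {
  data.frame(metadata_ref = character(), source_name = character(),
             source_version = character(), retrieval_date = character(),
             input_count = integer(), result_count = integer(),
             duration_seconds = numeric(), stringsAsFactors = FALSE)
}

emptyFailures <- function() {
  data.frame(source_name = character(), error_class = character(),
             message = character(), stringsAsFactors = FALSE)
}

failureRecord <- function(source_name, error_class, message) {
  data.frame(source_name = source_name, error_class = error_class,
             message = message, stringsAsFactors = FALSE)
}

#' Annotate a harmonized table against selected data sources
#'
#' Runs each selected source independently through the injected
#' transport, batching entities (default 25 per request, in input
#' order), parsing responses into typed annotation rows, and stamping
#' every batch with query metadata (source name and version, retrieval
#' date, input and result counts, wall-clock duration). A transport
#' failure for one source becomes an explicit failure record and never
#' aborts the other sources; selecting a source without a concrete
#' adapter is refused before any transport activity when the fetcher is
#' live.
#'
#' @param table a [HarmonizedTable-class].
#' @param selected character vector of source names.
#' @param fetcher transport function(request) -> response; typically
#'   [fixtureFetcher()] in tests and demos.
#' @param batch_size positive integer, identifiers per request.
#' @param catalog source catalog.
#' @return list with elements `rows` (annotation data.frame), `metadata`
#'   (query-metadata data.frame) and `failures` (failure report
#'   data.frame).
#' @export
annotateTable <- function(table, selected, fetcher, batch_size = 25L,
                          catalog = defaultCatalog()) {
  stopifnot(is(table, "HarmonizedTable"), batch_size >= 1L)
  unknown <- setdiff(selected, catalog$name)
  if (length(unknown))
    stopf("unknown data source(s): %s", paste(unknown, collapse = ", "),
          class = "ckg_lookup_error")
  is_fixture <- inherits(fetcher, "ckgFixtureFetcher")
  non_concrete <- selected[!catalog$concrete[match(selected, catalog$name)]]
  if (length(non_concrete) && !is_fixture)
    stopf("source(s) without a concrete adapter cannot be queried live: %s",
          paste(non_concrete, collapse = ", "),
          class = "ckg_unsupported_source_error")

  hr <- harmonizedRows(table)
  keys <- hr$canonical_key
  xrefs <- stats::setNames(hr$xrefs, keys)
  version <- attr(fetcher, "source_version") %||% "unknown"
  rdate <- attr(fetcher, "retrieval_date") %||% format(Sys.Date())

  all_rows <- list()
  all_meta <- list()
  failures <- list()

  for (src in sortC(unique(selected))) {
    if (src %in% non_concrete) {
      failures[[length(failures) + 1L]] <- failureRecord(
        src, "ckg_unsupported_source_error",
        "no concrete adapter; catalog stub cannot be queried")
      next
    }
    src_keys <- keys
    if (!length(src_keys)) next
    batches <- split(src_keys,
                     ceiling(seq_along(src_keys) / batch_size))
    for (bi in seq_along(batches)) {
      ref <- sprintf("%s#%d", src, bi)
      req <- buildRequest(src, batches[[bi]], xrefs, catalog)
      for (sk in req$skipped) {
        failures[[length(failures) + 1L]] <- failureRecord(
          src, "ckg_missing_translation",
          sprintf("no %s cross-reference for %s",
                  sourceNamespaces()[[src]], sk))
      }
      if (!length(req$entity_batch)) next
      t0 <- proc.time()[["elapsed"]]
      resp <- tryCatch(fetcher(req), error = function(e) e)
      if (inherits(resp, "error")) {
        failures[[length(failures) + 1L]] <- failureRecord(
          src, class(resp)[1L], conditionMessage(resp))
        break  # abandon remaining batches of this source only
      }
      rows <- tryCatch(
        parseResponse(src, resp, req$entity_batch, xrefs),
        error = function(e) e)
      if (inherits(rows, "error")) {
        failures[[length(failures) + 1L]] <- failureRecord(
          src, class(rows)[1L], conditionMessage(rows))
        break
      }
      dur <- proc.time()[["elapsed"]] - t0
      if (nrow(rows)) rows$metadata_ref <- ref
      all_rows[[length(all_rows) + 1L]] <- rows
      all_meta[[length(all_meta) + 1L]] <- data.frame(
        metadata_ref = ref, source_name = src, source_version = version,
        retrieval_date = rdate,
        input_count = length(req$entity_batch),
        result_count = nrow(rows), duration_seconds = dur,
        stringsAsFactors = FALSE)
    }
  }

  rows <- bindAnnotationRows(all_rows)
  meta <- if (length(all_meta)) do.call(rbind, all_meta)
          else emptyQueryMetadata()
  fails <- if (length(failures)) do.call(rbind, failures)
           else emptyFailures()
  rownames(meta) <- rownames(fails) <- NULL
  list(rows = rows, metadata = meta, failures = fails)
}

#' Write the per-source failure report as JSON lines
#'
#' @param failures failure data.frame from [annotateTable()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeFailureReport <- function(failures, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(failures))) {
    writeLines(as.character(jsonlite::toJSON(as.list(failures[i, ]),
                                             auto_unbox = TRUE)), con)
  }
  invisible(path)
}
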