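#' Parse user input into uniform records
#'
#' Accepts the three supported input kinds: a plain list of gene/protein
#' identifiers, a plain list of metabolite/compound identifiers (one
#' token per line, optional `NS:accession` CURIE form), or a
#' differential-expression (DEA) result table with identifier, effect
#' size (log2 fold-change) and significance (p-value) columns. Blank
#' lines are dropped, order is preserved and duplicates retained —
#' deduplication happens at mapping time.
#'
#' @param raw a file path, a character vector of lines (lists), or a
#'   data.frame (DEA table).
#' @param input_kind one of [inputKinds()].
#' @param column_map named list overriding DEA column names; defaults
#'   `list(identifier = "identifier", effect = "log2fc",
#'   significance = "p_value")`.
#' @return data.frame of input records: raw_identifier,
#'   declared_namespace, entity_kind, effect_size, significance.
#' @export
#' @examples
#' parseInput(c("TP53", "CXCL10"), "gene_list")
parseInput <- function(raw, input_kind,
                       column_map = list(identifier = "identifier",
                                         effect = "log2fc",
                                         significance = "p_value")) {
  kinds <- inputKinds()
  if (length(input_kind) != 1L || !input_kind %in% kinds)
    stopf("unsupported input kind '%s' (supported: %s)",
          paste(input_kind, collapse = ","), paste(kinds, collapse = ", "),
          class = "ckg_unsupported_kind_error")

  if (input_kind %in% c("gene_list", "metabolite_list")) {
    lines <- readInputLines(raw)
    lines <- trimws2(lines)
    lines <- lines[nzchar(lines)]
    cur <- splitCurie(lines)
    kind <- if (input_kind == "gene_list") "gene" else "metabolite"
    out <- data.frame(raw_identifier = lines,
                      declared_namespace = cur$namespace,
                      entity_kind = rep(kind, length(lines)),
                      effect_size = rep(NA_real_, length(lines)),
                      significance = rep(NA_real_, length(lines)),
                      stringsAsFactors = FALSE)
    return(out)
  }

  # dea_table
  tab <- readInputTable(raw)
  cm <- utils::modifyList(list(identifier = "identifier", effect = "log2fc",
                               significance = "p_value"),
                          as.list(column_map %||% list()))
  if (!cm$identifier %in% names(tab))
    stopf("DEA table is missing identifier column '%s'", cm$identifier,
          class = "ckg_schema_error")
  ids <- trimws2(as.character(tab[[cm$identifier]]))
  keep <- nzchar(ids) & !is.na(ids)
  tab <- tab[keep, , drop = FALSE]
  ids <- ids[keep]
  eff <- parseNumericColumn(tab, cm$effect, "effect")
  sig <- parseNumericColumn(tab, cm$significance, "significance")
  if (any(!is.na(sig) & (sig < 0 | sig > 1)))
    stopf("significance values outside [0,1] at row(s) %s",
          paste(which(!is.na(sig) & (sig < 0 | sig > 1)), collapse = ", "),
          class = "ckg_parse_error")
  cur <- splitCurie(ids)
  data.frame(raw_identifier = ids,
             declared_namespace = cur$namespace,
             entity_kind = rep("gene", length(ids)),
             effect_size = eff,
             significance = sig,
             stringsAsFactors = FALSE)
}

readInputLines <- function(raw) {
  if (is.character(raw) && length(raw) == 1L && file.exists(raw))
    return(readLines(raw, warn = FALSE, encoding = "UTF-8"))
  if (is.character(raw)) return(raw)
  if (is.data.frame(raw)) return(as.character(raw[[1L]]))
  stopf("cannot read identifier list from object of class %s",
        paste(class(raw), collapse = "/"), class = "ckg_parse_error")
}

readInputTable <- function(raw) {
  if (is.data.frame(raw)) return(raw)
  if (is.character(raw) && length(raw) == 1L && file.exists(raw)) {
    first <- readLines(raw, n = 1L, warn = FALSE)
    sep <- if (grepl("\t", first)) "\t" else ","
    return(utils::read.table(raw, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, check.names = FALSE,
                             quote = "\"", comment.char = ""))
  }
  stopf("DEA input must be a data.frame or an existing file path",
        class = "ckg_parse_error")
}

parseNumericColumn <- function(tab, column, what) {
  if (is.null(column) || !column %in% names(tab))
    return(rep(NA_real_, nrow(tab)))
  v <- tab[[column]]
  if (is.numeric(v)) return(as.numeric(v))
  out <- suppressWarnings(as.numeric(v))
  bad <- which(!is.na(v) & nzchar(trimws2(as.character(v))) & is.na(out))
  if (length(bad))
    stopf("non-numeric %s value '%s' at row %d", what,
          as.character(v[bad[1L]]), bad[1L], class = "ckg_parse_error")
  out
}

#' Load an identifier mapping table
#'
#' Local mode reads a 4-column tab-separated file (source_namespace,
#' source_id, target_namespace, target_id; header required) and stamps
#' the result with the file name and its MD5 checksum. Remote mode calls
#' the injected `fetcher` with the descriptor and expects the same TSV
#' text back, stamping service name and retrieval date instead. One
#' source identifier may map to several targets.
#'
#' @param source path to a local mapping TSV, or (remote mode) a list
#'   with at least a `name` element describing the service.
#' @param fetcher optional function(source) returning TSV text; required
#'   for remote mode, ignored for local files.
#' @return data.frame of mappings with attribute `"provenance"`.
#' @export
loadMappingTable <- function(source, fetcher = NULL) {
  if (is.character(source) && length(source) == 1L) {
    if (!file.exists(source))
      stopf("mapping file '%s' does not exist", source,
            class = "ckg_config_error")
    lines <- readLines(source, warn = FALSE, encoding = "UTF-8")
    prov <- sprintf("file:%s md5:%s", basename(source),
                    unname(tools::md5sum(source)))
  } else if (is.list(source)) {
    if (is.null(fetcher))
      stopf("remote mapping source requires an injected fetcher",
            class = "ckg_config_error")
    lines <- strsplit(fetcher(source), "\n", fixed = TRUE)[[1L]]
    prov <- sprintf("service:%s date:%s", source$name %||% "unnamed",
                    format(Sys.Date()))
  } else {
    stopf("mapping source must be a file path or a service descriptor",
          class = "ckg_config_error")
  }
  lines <- lines[nzchar(trimws2(lines))]
  if (!length(lines))
    stopf("mapping file has no header line", class = "ckg_parse_error")
  body <- lines[-1L]
  maps <- emptyMappings()
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    nfield <- lengths(parts)
    bad <- which(nfield != 4L)
    if (length(bad))
      stopf("malformed mapping row at line %d: expected 4 tab-separated fields, got %d",
            bad[1L] + 1L, nfield[bad[1L]], class = "ckg_parse_error")
    m <- do.call(rbind, parts)
    maps <- data.frame(source_namespace = toupper(trimws2(m[, 1L])),
                       source_id = trimws2(m[, 2L]),
                       target_namespace = toupper(trimws2(m[, 3L])),
                       target_id = trimws2(m[, 4L]),
                       stringsAsFactors = FALSE)
    if (any(!nzchar(maps$source_namespace) | !nzchar(maps$source_id) |
            !nzchar(maps$target_namespace) | !nzchar(maps$target_id)))
      stopf("mapping rows contain empty fields", class = "ckg_parse_error")
  }
  attr(maps, "provenance") <- prov
  maps
}

emptyMappings <- function() {
  data.frame(source_namespace = character(), source_id = character(),
             target_namespace = character(), target_id = character(),
             stringsAsFactors = FALSE)
}

#' Map input records onto canonical namespaces
#'
#' Every distinct input identifier is resolved against the mapping table:
#' directly (source namespace to target namespace) and through one pivot
#' hop via `hub_namespace`; deeper transitive chains are deliberately not
#' followed. A record whose identifier is already in the target namespace
#' maps to itself. When one source id reaches several target accessions,
#' the lexicographically first becomes the canonical key and the rest are
#' kept as cross-references (the choice is recorded in the provenance
#' string). Duplicate inputs that land on the same canonical key merge:
#' silently when their DEA statistics agree, with a merge-conflict error
#' when they do not.
#'
#' @param records data.frame from [parseInput()].
#' @param mappings data.frame from [loadMappingTable()] (may be empty).
#' @param target_namespace_policy named character vector, entity kind to
#'   namespace; defaults to [defaultNamespacePolicy()].
#' @param hub_namespace namespace used for the single pivot hop
#'   (default "HGNC").
#' @return a [HarmonizedTable-class] object.
#' @export
mapIdentifiers <- function(records, mappings = emptyMappings(),
                           target_namespace_policy = defaultNamespacePolicy(),
                           hub_namespace = "HGNC") {
  kinds <- unique(records$entity_kind)
  missing_kind <- setdiff(kinds, names(target_namespace_policy))
  if (length(missing_kind))
    stopf("no target namespace configured for entity kind(s): %s",
          paste(missing_kind, collapse = ", "), class = "ckg_config_error")
  target_namespace_policy <- toupper(target_namespace_policy)
  hub_namespace <- toupper(hub_namespace)

  rows <- list()
  unmapped <- list()
  if (nrow(records)) {
    cur <- splitCurie(records$raw_identifier)
    records$src_ns <- ifelse(!is.na(records$declared_namespace),
                             toupper(records$declared_namespace),
                             cur$namespace)
    records$accession <- ifelse(!is.na(cur$namespace), cur$accession,
                                records$raw_identifier)
    dup_key <- paste(records$raw_identifier, records$entity_kind, sep = "\r")
    for (i in seq_len(nrow(records))) {
      if (i > 1L && dup_key[i] %in% dup_key[seq_len(i - 1L)]) {
        # same raw identifier seen before: merge handled below via
        # canonical-key collision; still must check DEA agreement there
      }
      rec <- records[i, , drop = FALSE]
      target <- target_namespace_policy[[rec$entity_kind]]
      res <- resolveOne(rec$src_ns, rec$accession, target, mappings,
                        hub_namespace)
      if (is.null(res)) {
        unmapped[[length(unmapped) + 1L]] <- data.frame(
          raw_identifier = rec$raw_identifier,
          declared_namespace = rec$declared_namespace,
          entity_kind = rec$entity_kind,
          reason = sprintf("no mapping chain to %s", target),
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- list(
          canonical_key = res$canonical_key,
          raw_identifier = rec$raw_identifier,
          declared_namespace = rec$declared_namespace,
          entity_kind = rec$entity_kind,
          effect_size = rec$effect_size,
          significance = rec$significance,
          xrefs = res$xrefs)
      }
    }
  }

  merged <- mergeHarmonizedRows(rows)
  un <- if (length(unmapped)) unique(do.call(rbind, unmapped)) else emptyUnmapped()
  prov <- attr(mappings, "provenance") %||% "none"
  prov <- paste0(prov, "; one-to-many resolved to lexicographic minimum; ",
                 "pivot hub=", hub_namespace)
  new("HarmonizedTable", rows = merged, unmapped = un, provenance = prov)
}

# resolve one (namespace, accession) to the target namespace.
# Returns NULL when unreachable, else list(canonical_key, xrefs).
resolveOne <- function(src_ns, accession, target, mappings, hub) {
  xrefs <- character()
  if (!is.na(src_ns)) xrefs[src_ns] <- accession

  hits <- if (nrow(mappings)) {
    sel <- mappings$source_id == accession &
      (is.na(src_ns) | mappings$source_namespace == src_ns)
    mappings[sel, , drop = FALSE]
  } else mappings

  # direct cross-references
  if (nrow(hits)) {
    xr <- stats::setNames(hits$target_id, hits$target_namespace)
    xrefs <- c(xrefs, xr)
  }
  # one pivot hop through the hub namespace
  hub_ids <- hits$target_id[hits$target_namespace == hub]
  if (!is.na(src_ns) && src_ns == hub) hub_ids <- c(hub_ids, accession)
  if (length(hub_ids) && nrow(mappings)) {
    sel2 <- mappings$source_namespace == hub & mappings$source_id %in% hub_ids
    hop <- mappings[sel2, , drop = FALSE]
    if (nrow(hop))
      xrefs <- c(xrefs, stats::setNames(hop$target_id, hop$target_namespace))
  }

  targets <- character()
  if (!is.na(src_ns) && src_ns == target) targets <- accession
  targets <- c(targets, unname(xrefs[names(xrefs) == target]))
  targets <- sortC(unique(targets))
  if (!length(targets)) return(NULL)

  canonical <- targets[1L]
  xrefs[target] <- canonical
  # keep non-canonical same-namespace targets as extra xrefs too
  extra <- setdiff(targets, canonical)
  if (length(extra))
    xrefs <- c(xrefs, stats::setNames(extra, rep(target, length(extra))))
  xrefs <- dedupXrefs(xrefs)
  list(canonical_key = canonicalKey(target, canonical), xrefs = xrefs)
}

dedupXrefs <- function(xrefs) {
  if (!length(xrefs)) return(character())
  key <- paste(names(xrefs), xrefs, sep = "\r")
  xrefs <- xrefs[!duplicated(key)]
  xrefs[orderC(names(xrefs), xrefs)]
}

mergeHarmonizedRows <- function(rows) {
  out <- emptyHarmonizedRows()
  out$xrefs <- list()
  if (!length(rows)) return(out)
  keys <- vapply(rows, function(r) r$canonical_key, character(1))
  by_key <- split(seq_along(rows), keys)
  # preserve first-appearance order of canonical keys
  first_pos <- vapply(by_key, min, integer(1))
  by_key <- by_key[orderC(first_pos)]
  acc <- lapply(by_key, function(idx) {
    grp <- rows[idx]
    eff <- unique(stats::na.omit(vapply(grp, function(r) r$effect_size, numeric(1))))
    sig <- unique(stats::na.omit(vapply(grp, function(r) r$significance, numeric(1))))
    if (length(eff) > 1L || length(sig) > 1L)
      stopf("conflicting DEA statistics for canonical key %s (raw ids: %s)",
            grp[[1L]]$canonical_key,
            paste(unique(vapply(grp, function(r) r$raw_identifier,
                                character(1))), collapse = ", "),
            class = "ckg_merge_conflict_error")
    list(canonical_key = grp[[1L]]$canonical_key,
         raw_identifier = grp[[1L]]$raw_identifier,
         declared_namespace = grp[[1L]]$declared_namespace,
         entity_kind = grp[[1L]]$entity_kind,
         effect_size = if (length(eff)) eff else NA_real_,
         significance = if (length(sig)) sig else NA_real_,
         xrefs = dedupXrefs(do.call(c, lapply(grp, function(r) r$xrefs))))
  })
  out <- data.frame(
    canonical_key = vapply(acc, `[[`, character(1), "canonical_key"),
    raw_identifier = vapply(acc, `[[`, character(1), "raw_identifier"),
    declared_namespace = vapply(acc, `[[`, character(1), "declared_namespace"),
    entity_kind = vapply(acc, `[[`, character(1), "entity_kind"),
    effect_size = vapply(acc, `[[`, numeric(1), "effect_size"),
    significance = vapply(acc, `[[`, numeric(1), "significance"),
    stringsAsFactors = FALSE)
  out$xrefs <- lapply(acc, `[[`, "xrefs")
  rownames(out) <- NULL
  out
}

#' Write the unmapped-identifier report
#'
#' @param table a HarmonizedTable.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeUnmappedReport <- function(table, path) {
  un <- unmappedRecords(table)
  utils::write.table(un[, c("raw_identifier", "reason")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
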