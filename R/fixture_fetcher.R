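#' Candidate entity pools used by the fixture transport
#'
#' Small fixed pools of diseases, compounds, pathways and anatomical
#' entities from which the fixture fetcher samples when synthesizing
#' source responses. Labels are real biomedical terms (post-viral
#' symptoms, common drugs, tissues) so demo graphs read naturally, but
#' the pools are synthetic test data, not a snapshot of any database.
#'
#' @return named list of data.frames.
#' @export
fixturePools <- function() {
  list(
    diseases = data.frame(
      umls = c("C0015672", "C0231528", "C0010200"),
      efo = c("EFO_0003843", "EFO_0004243", "EFO_0003949"),
      name = c("Fatigue", "Myalgia", "Coughing"),
      stringsAsFactors = FALSE),
    compounds = data.frame(
      chembl = c("CHEMBL112", "CHEMBL25", "CHEMBL1431"),
      cid = c("1983", "2244", "4091"),
      name = c("Acetaminophen", "Aspirin", "Metformin"),
      stringsAsFactors = FALSE),
    pathways = data.frame(
      wp = c("WP4868", "WP554", "WP1533"),
      name = c("Type I interferon induction", "ACE inhibitor pathway",
               "Vitamin B12 metabolism"),
      stringsAsFactors = FALSE),
    minerva_pathways = data.frame(
      id = c("101", "102", "103"),
      name = c("Interferon signalling", "Complement cascade",
               "TGF-beta signalling"),
      stringsAsFactors = FALSE),
    anatomy = data.frame(
      uberon = c("UBERON_0000948", "UBERON_0002113", "UBERON_0002048"),
      name = c("heart", "kidney", "lung"),
      stage = c("adult", "adult", "infant"),
      stringsAsFactors = FALSE)
  )
}

#' Deterministic fixture transport
#'
#' Returns an injectable transport that, for each concrete source,
#' synthesizes a syntactically valid response in that source's dialect
#' (REST JSON, GraphQL result JSON, SPARQL results JSON). Each
#' (input entity, candidate object) pair from [fixturePools()] is
#' included with probability `density` under a pseudo-random stream
#' keyed by (seed, source name, entity key, candidate), so identical
#' inputs always yield byte-identical responses and no global RNG state
#' is touched.
#'
#' @param seed integer stream key.
#' @param density inclusion probability in `[0, 1]`.
#' @return a function(request) -> raw response list(source_name, body,
#'   status), classed `"ckgFixtureFetcher"`, carrying `source_version`
#'   (`"fixture-<seed>"`) and a fixed `retrieval_date` attribute so
#'   downstream exports are reproducible.
#' @export
#' @examples
#' f <- fixtureFetcher(seed = 7, density = 1)
#' attr(f, "source_version")
fixtureFetcher <- function(seed, density = 0.5) {
  stopifnot(length(seed) == 1L, is.finite(seed),
            density >= 0, density <= 1)
  seed <- as.integer(seed)
  f <- function(request) {
    src <- request$source_name
    body <- switch(src,
      "DisGeNET" = fixtureDisgenetBody(seed, density, request),
      "OpenTargets" = fixtureOpentargetsBody(seed, density, request),
      "MINERVA" = fixtureMinervaBody(seed, density, request),
      "STRING" = fixtureStringBody(seed, density, request),
      "Bgee" = fixtureBgeeBody(seed, density, request),
      stopf("fixture transport has no response synthesizer for source '%s'",
            src, class = "ckg_unsupported_source_error"))
    list(source_name = src, body = body, status = 200L)
  }
  structure(f, class = c("ckgFixtureFetcher", "function"),
            seed = seed, density = density,
            source_version = sprintf("fixture-%d", seed),
            retrieval_date = "2026-01-15")
}

# inclusion decision for one (entity, candidate) pair
fixtureKeep <- function(seed, source, entity, candidate, density) {
  if (density <= 0) return(FALSE)
  if (density >= 1) return(TRUE)
  hashUnit(seed, source, entity, candidate) < density
}

# deterministic score in (0, 1), 3 decimals
fixtureScore <- function(seed, source, entity, candidate) {
  round(0.05 + 0.9 * hashUnit(seed, "score", source, entity, candidate), 3)
}

fixtureJson <- function(x) {
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

fixtureDisgenetBody <- function(seed, density, request) {
  pool <- fixturePools()$diseases
  recs <- list()
  for (k in seq_along(request$translated)) {
    acc <- request$translated[k]
    ent <- request$entity_batch[k]
    for (j in seq_len(nrow(pool))) {
      if (fixtureKeep(seed, "DisGeNET", ent, pool$umls[j], density)) {
        recs[[length(recs) + 1L]] <- list(
          geneid = acc,
          disease_umls = pool$umls[j],
          disease_name = pool$name[j],
          score = fixtureScore(seed, "DisGeNET", ent, pool$umls[j]))
      }
    }
  }
  fixtureJson(list(payload = recs))
}

fixtureOpentargetsBody <- function(seed, density, request) {
  pools <- fixturePools()
  targets <- list()
  for (k in seq_along(request$translated)) {
    acc <- request$translated[k]
    ent <- request$entity_batch[k]
    dis_rows <- list()
    for (j in seq_len(nrow(pools$diseases))) {
      dd <- pools$diseases[j, ]
      if (fixtureKeep(seed, "OpenTargets:disease", ent, dd$efo, density)) {
        dis_rows[[length(dis_rows) + 1L]] <- list(
          disease = list(id = dd$efo, name = dd$name,
                         dbXRefs = list(paste0("UMLS:", dd$umls))),
          score = fixtureScore(seed, "OpenTargets", ent, dd$efo))
      }
    }
    drug_rows <- list()
    for (j in seq_len(nrow(pools$compounds))) {
      cc <- pools$compounds[j, ]
      if (fixtureKeep(seed, "OpenTargets:drug", ent, cc$chembl, density)) {
        mech <- if (hashUnit(seed, "moa", ent, cc$chembl) < 0.5)
          "inhibitor" else "activator"
        dj <- 1L + (strHash(seed, "drugdis", ent, cc$chembl) %%
                      nrow(pools$diseases))
        dd <- pools$diseases[dj, ]
        drug_rows[[length(drug_rows) + 1L]] <- list(
          drug = list(id = cc$chembl, name = cc$name,
                      crossReferences = list(list(source = "PubChem",
                                                  reference = cc$cid))),
          mechanismOfAction = mech,
          disease = list(id = dd$efo, name = dd$name,
                         dbXRefs = list(paste0("UMLS:", dd$umls))))
      }
    }
    pw_rows <- list()
    for (j in seq_len(nrow(pools$pathways))) {
      pp <- pools$pathways[j, ]
      if (fixtureKeep(seed, "OpenTargets:pathway", ent, pp$wp, density)) {
        pw_rows[[length(pw_rows) + 1L]] <- list(pathwayId = pp$wp,
                                                pathway = pp$name)
      }
    }
    targets[[length(targets) + 1L]] <- list(
      id = acc,
      associatedDiseases = list(rows = dis_rows),
      knownDrugs = list(rows = drug_rows),
      pathways = pw_rows)
  }
  fixtureJson(list(data = list(targets = targets)))
}

fixtureMinervaBody <- function(seed, density, request) {
  pool <- fixturePools()$minerva_pathways
  recs <- list()
  for (k in seq_along(request$translated)) {
    acc <- request$translated[k]
    ent <- request$entity_batch[k]
    hits <- list()
    for (j in seq_len(nrow(pool))) {
      if (fixtureKeep(seed, "MINERVA", ent, pool$id[j], density)) {
        hits[[length(hits) + 1L]] <- list(id = pool$id[j],
                                          name = pool$name[j])
      }
    }
    recs[[length(recs) + 1L]] <- list(gene = acc, pathways = hits)
  }
  fixtureJson(recs)
}

fixtureStringBody <- function(seed, density, request) {
  # partner pool = other members of the same batch (unordered pairs)
  recs <- list()
  n <- length(request$translated)
  if (n >= 2L) {
    for (a in seq_len(n - 1L)) {
      for (b in seq((a + 1L), n)) {
        pair <- sortC(c(request$entity_batch[a], request$entity_batch[b]))
        if (fixtureKeep(seed, "STRING", pair[1L], pair[2L], density)) {
          recs[[length(recs) + 1L]] <- list(
            stringId_A = request$translated[a],
            stringId_B = request$translated[b],
            preferredName_A = request$entity_batch[a],
            preferredName_B = request$entity_batch[b],
            score = fixtureScore(seed, "STRING", pair[1L], pair[2L]))
        }
      }
    }
  }
  fixtureJson(recs)
}

fixtureBgeeBody <- function(seed, density, request) {
  pool <- fixturePools()$anatomy
  bindings <- list()
  for (k in seq_along(request$translated)) {
    acc <- request$translated[k]
    ent <- request$entity_batch[k]
    for (j in seq_len(nrow(pool))) {
      if (fixtureKeep(seed, "Bgee", ent, pool$uberon[j], density)) {
        over <- hashUnit(seed, "bgee_dir", ent, pool$uberon[j]) < 0.5
        bindings[[length(bindings) + 1L]] <- list(
          gene = list(type = "literal", value = acc),
          anat = list(type = "uri",
                      value = paste0("http://purl.obolibrary.org/obo/",
                                     pool$uberon[j])),
          anatName = list(type = "literal", value = pool$name[j]),
          level = list(type = "literal",
                       value = as.character(round(
                         100 * hashUnit(seed, "bgee_lvl", ent,
                                        pool$uberon[j]), 1))),
          stage = list(type = "literal", value = pool$stage[j]),
          over = list(type = "literal",
                      value = if (over) "true" else "false"))
      }
    }
  }
  fixtureJson(list(
    head = list(vars = list("gene", "anat", "anatName", "level", "stage",
                            "over")),
    results = list(bindings = bindings)))
}

#' Wrap a transport so that selected sources fail
#'
#' Test utility for the failure-isolation contract: the returned
#' transport raises a simulated transport error for `fail_sources` and
#' delegates everything else to `fetcher` unchanged.
#'
#' @param fetcher inner transport.
#' @param fail_sources character vector of source names to fail.
#' @return transport function with the same class attributes as
#'   `fetcher`.
#' @export
failingFetcher <- function(fetcher, fail_sources) {
  out <- function(request) {
    if (request$source_name %in% fail_sources)
      stopf("simulated transport failure for %s", request$source_name,
            class = "ckg_transport_error")
    fetcher(request)
  }
  attributes(out) <- attributes(fetcher)
  out
}
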