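#' Closed node-type vocabulary
#'
#' The knowledge-graph data model covers exactly 18 node types spanning
#' core biological entities (gene, disease, compound), functional
#' annotation (pathway and the three Gene Ontology branches), tissue
#' context (anatomical entity), regulatory actors (miRNA, transcription
#' factor), and the adverse-outcome-pathway chain (key event, molecular
#' initiating event, adverse outcome pathway, adverse outcome). Proteins
#' are not distinct nodes; protein-level assertions are folded onto gene
#' nodes.
#'
#' @return character vector of the 18 node-type labels.
#' @export
#' @examples
#' nodeTypeVocabulary()
nodeTypeVocabulary <- function() {
  c("gene", "disease", "compound", "anatomical_entity", "pathway",
    "molecular_function", "biological_process", "cellular_component",
    "side_effect", "homolog", "phenotype", "mirna",
    "transcription_factor", "mitochondrial_pathway", "key_event",
    "molecular_initiating_event", "adverse_outcome_pathway",
    "adverse_outcome")
}

#' Closed edge-relation vocabulary
#'
#' All edges are directed and typed with one of exactly 10 relations.
#'
#' @return character vector of the 10 relation labels.
#' @export
#' @examples
#' relationVocabulary()
relationVocabulary <- function() {
  c("interacts_with", "part_of", "associated_with", "expressed_by",
    "activates", "inhibits", "treats", "has_side_effect",
    "upstream_of", "downstream_of")
}

#' Supported input kinds
#'
#' Three kinds of user input are accepted: a plain gene/protein identifier
#' list, a metabolite/compound identifier list, and a
#' differential-expression analysis (DEA) result table whose effect-size
#' and significance columns are carried into the graph as gene attributes.
#'
#' @return character vector of the 3 input kinds.
#' @export
inputKinds <- function() {
  c("gene_list", "metabolite_list", "dea_table")
}

#' Supported export formats
#'
#' @return character vector of the 3 serialization formats.
#' @export
exportFormats <- function() {
  c("cytoscape", "graphml", "rdf")
}

assertNodeType <- function(x) {
  bad <- setdiff(unique(x), nodeTypeVocabulary())
  if (length(bad))
    stopf("unknown node type(s): %s", paste(bad, collapse = ", "),
          class = "ckg_vocabulary_error")
  invisible(x)
}

assertRelation <- function(x) {
  bad <- setdiff(unique(x), relationVocabulary())
  if (length(bad))
    stopf("unknown relation(s): %s", paste(bad, collapse = ", "),
          class = "ckg_vocabulary_error")
  invisible(x)
}

#' Default canonical namespace per entity kind
#'
#' Genes are keyed by Entrez gene identifiers, metabolites/compounds by
#' PubChem CIDs; diseases contributed by annotators are keyed by UMLS
#' CUIs. Override by passing a named character vector wherever a
#' `target_namespace_policy` argument is accepted.
#'
#' @return named character vector mapping entity kind to namespace.
#' @export
defaultNamespacePolicy <- function() {
  c(gene = "ENTREZ", metabolite = "PUBCHEM")
}
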