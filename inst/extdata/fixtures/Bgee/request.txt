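PREFIX genex: <http://purl.org/genex#>
PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>
SELECT ?gene ?anat ?anatName ?level ?stage ?over WHERE {
  VALUES ?gene { "ENSG00000141510" }
  ?expr genex:hasSequenceUnit ?gene ;
        genex:hasAnatomicalEntity ?anat ;
        genex:hasExpressionLevel ?level ;
        genex:hasDevelopmentalStage ?stage ;
        genex:isOverExpressed ?over .
  ?anat rdfs:label ?anatName .
}

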