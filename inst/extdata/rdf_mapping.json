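{
  "version": "1",
  "comment": "Correspondence from graph node types to ontology classes and from edge relations to predicates. associated_with maps to a SIO association class and is reified as an association node with sio:has_part participants; activates/inhibits use Relation Ontology regulation predicates.",
  "node_classes": {
    "gene": "http://semanticscience.org/resource/SIO_010035",
    "disease": "http://semanticscience.org/resource/SIO_010299",
    "compound": "http://semanticscience.org/resource/SIO_010004",
    "anatomical_entity": "http://purl.obolibrary.org/obo/UBERON_0001062",
    "pathway": "http://purl.obolibrary.org/obo/PW_0000001",
    "molecular_function": "http://purl.obolibrary.org/obo/GO_0003674",
    "biological_process": "http://purl.obolibrary.org/obo/GO_0008150",
    "cellular_component": "http://purl.obolibrary.org/obo/GO_0005575",
    "side_effect": "http://purl.obolibrary.org/obo/OAE_0000001",
    "homolog": "http://semanticscience.org/resource/SIO_010077",
    "phenotype": "http://purl.obolibrary.org/obo/HP_0000118",
    "mirna": "http://purl.obolibrary.org/obo/SO_0000276",
    "transcription_factor": "http://purl.obolibrary.org/obo/NCIT_C17207",
    "mitochondrial_pathway": "http://purl.obolibrary.org/obo/PW_0000002",
    "key_event": "http://aopkb.org/aop_ontology#KeyEvent",
    "molecular_initiating_event": "http://aopkb.org/aop_ontology#MolecularInitiatingEvent",
    "adverse_outcome_pathway": "http://aopkb.org/aop_ontology#AdverseOutcomePathway",
    "adverse_outcome": "http://aopkb.org/aop_ontology#AdverseOutcome"
  },
  "relation_predicates": {
    "interacts_with": "http://purl.obolibrary.org/obo/RO_0002434",
    "part_of": "http://purl.obolibrary.org/obo/BFO_0000050",
    "associated_with": "http://semanticscience.org/resource/SIO_000897",
    "expressed_by": "http://purl.obolibrary.org/obo/RO_0002206",
    "activates": "http://purl.obolibrary.org/obo/RO_0011005",
    "inhibits": "http://purl.obolibrary.org/obo/RO_0011009",
    "treats": "http://purl.obolibrary.org/obo/RO_0002606",
    "has_side_effect": "http://purl.obolibrary.org/obo/OAE_0004001",
    "upstream_of": "http://purl.obolibrary.org/obo/RO_0002411",
    "downstream_of": "http://purl.obolibrary.org/obo/RO_0002404"
  }
}
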