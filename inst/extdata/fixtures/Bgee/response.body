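{"head": {"vars": ["gene", "anat", "anatName", "level", "stage", "over"]},
 "results": {"bindings": [
   {"gene": {"type": "literal", "value": "ENSG00000141510"},
    "anat": {"type": "uri", "value": "http://purl.obolibrary.org/obo/UBERON_0000948"},
    "anatName": {"type": "literal", "value": "heart"},
    "level": {"type": "literal", "value": "23.4"},
    "stage": {"type": "literal", "value": "adult"},
    "over": {"type": "literal", "value": "true"}}
 ]}}
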