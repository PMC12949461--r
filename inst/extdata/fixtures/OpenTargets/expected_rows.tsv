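subject_key	relation	object_key	object_type	object_label
ENTREZ:7157	associated_with	UMLS:C0015672	disease	Fatigue
PUBCHEM:1983	inhibits	ENTREZ:7157	gene	ENTREZ:7157
PUBCHEM:1983	treats	UMLS:C0015672	disease	Fatigue
ENTREZ:7157	part_of	WIKIPATHWAYS:WP4868	pathway	Type I interferon induction
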