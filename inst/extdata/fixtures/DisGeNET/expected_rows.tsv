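subject_key	relation	object_key	object_type	object_label
ENTREZ:7157	associated_with	UMLS:C0015672	disease	Fatigue
ENTREZ:3569	associated_with	UMLS:C0231528	disease	Myalgia
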