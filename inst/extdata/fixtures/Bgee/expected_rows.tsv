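subject_key	relation	object_key	object_type	object_label
ENTREZ:7157	expressed_by	UBERON:0000948	anatomical_entity	heart
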