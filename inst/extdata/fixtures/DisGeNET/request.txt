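https://api.disgenet.example/api/v1/gda/summary?gene_ncbi_id=7157,3569
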