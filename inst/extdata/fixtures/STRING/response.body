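[{"stringId_A": "9606.ENSP00000269305", "stringId_B": "9606.ENSP00000258743",
  "preferredName_A": "TP53", "preferredName_B": "IL6", "score": 0.95}]
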