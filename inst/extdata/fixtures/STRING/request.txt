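https://string.example/api/json/network?identifiers=9606.ENSP00000269305%0d9606.ENSP00000258743&species=9606
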