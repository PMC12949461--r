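{"payload": [
  {"geneid": "7157", "disease_umls": "C0015672", "disease_name": "Fatigue", "score": 0.42},
  {"geneid": "3569", "disease_umls": "C0231528", "disease_name": "Myalgia", "score": 0.31}
]}
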