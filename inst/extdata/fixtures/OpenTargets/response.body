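{"data": {"targets": [
  {"id": "ENSG00000141510",
   "associatedDiseases": {"rows": [
     {"disease": {"id": "EFO_0003843", "name": "Fatigue", "dbXRefs": ["UMLS:C0015672"]}, "score": 0.77}
   ]},
   "knownDrugs": {"rows": [
     {"drug": {"id": "CHEMBL112", "name": "Acetaminophen",
               "crossReferences": [{"source": "PubChem", "reference": "1983"}]},
      "mechanismOfAction": "inhibitor",
      "disease": {"id": "EFO_0003843", "name": "Fatigue", "dbXRefs": ["UMLS:C0015672"]}}
   ]},
   "pathways": [{"pathwayId": "WP4868", "pathway": "Type I interferon induction"}]
  }
]}}
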