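query annotateTargets {
  targets(ensemblIds: ["ENSG00000141510"]) {
    id
    associatedDiseases { rows { disease { id name dbXRefs } score } }
    knownDrugs { rows { drug { id name crossReferences { source reference } } mechanismOfAction disease { id name dbXRefs } } }
    pathways { pathwayId pathway }
  }
}

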