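{
  "structures_total": 239149,
  "structures_with_halogenated_aryl_ligand": 9810,
  "corpus_date": "2025-07"
}
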