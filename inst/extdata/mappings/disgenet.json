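{
  "gene_col": "gene_symbol",
  "disease_col": "disease_id",
  "disease_name_col": "disease_name",
  "score_col": "score"
}
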