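{
  "accession_field": "accession",
  "name_field": "full_name",
  "gene_field": "gene",
  "epitopes_field": "epitopes"
}
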