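{
  "symbol_field": "symbol",
  "ncbi_field": "ncbi_id",
  "location_field": "location",
  "uniprot_field": "uniprot"
}
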