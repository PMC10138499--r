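{
  "epitope_col": "epitope_seq",
  "type_col": "epitope_type",
  "antigen_col": "antigen_id",
  "taxon_col": "organism_taxon"
}
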