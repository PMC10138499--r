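{
  "accession_field": "acc",
  "disprot_id_field": "disprot_id",
  "disorder_field": "disorder_content",
  "taxon_field": "taxon"
}
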