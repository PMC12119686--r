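{
  "acl_igg": 10,
  "acl_igm": 10,
  "b2gpi_igg": 8,
  "b2gpi_igm": 8,
  "units": "U/ml",
  "note": "kit-style recommended cutoffs; positivity is strictly greater-than"
}
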