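{
  "name": "PEAR_GFP_synthetic",
  "spacer": "GTCACCTCCAATGACTAGGG",
  "edit": {
    "kind": "substitution",
    "position": 47,
    "ref_allele": "AC",
    "alt_allele": "GT"
  }
}
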