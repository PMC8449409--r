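{
  "comment": "Editable segment boundaries (1-based, inclusive) for the synthetic stand-in tail sequence shipped as ecad_tail_synthetic.fasta.",
  "A": [1, 70],
  "B": [71, 124],
  "C": [125, 148],
  "AB": [1, 124],
  "BC": [71, 148],
  "ABC": [1, 148]
}
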