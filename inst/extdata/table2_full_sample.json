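{
  "X->C1": 0.070, "X->A": 0.026,
  "C1->X": 0.582, "C1->A": 0.096,
  "A->C2": 0.221, "A->R": 0.508,
  "C2->A": 0.200, "C2->R": 0.455,
  "R->C2": 0.127, "R->A": 0.108, "R->X": 0.288,
  "label": "full sample"
}
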