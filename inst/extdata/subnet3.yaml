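# 3-gene cascade preset (genes g6, g7, g8; g7 inhibits g8)
genes:
- g6
- g7
- g8
reactions:
- regulator: g7
  target: g8
  sign: inhibition
mrna_degradation:
  g6: 1.0
  g7: 1.0
  g8: 1.0
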