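name: combined_depletion
genotype: NZBW
schedule:
  polyic_window: [19.0, 23.0]
  depletion_targets: [tILC, vNK]
  depletion_strength: 0.8
  depletion_window: [19.0, 25.0]
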