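name: nzbw_polyic
genotype: NZBW
schedule:
  polyic_window: [19.0, 23.0]
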