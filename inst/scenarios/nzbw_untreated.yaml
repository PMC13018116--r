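name: nzbw_untreated
genotype: NZBW
schedule:
  polyic_window: ~
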