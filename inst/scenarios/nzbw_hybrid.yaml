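# untreated lupus-prone mice with spontaneous acute inflammatory events
name: nzbw_hybrid
genotype: NZBW
schedule:
  polyic_window: ~
telegraph:
  tau_on: 7.0
  tau_off: 35.0
  cv_on: 0.5
  xi: 0.13
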