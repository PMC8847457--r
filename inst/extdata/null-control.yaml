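# Light-stable null control: identical acquisition, all kinetics zeroed.
scenario: null_control
model: {}
kinetics:
  ise_drop: 0.0
  elmrpe_shortening_um: 0.0
  onl_shortening_um: 0.0
  iz_contrast_loss: 0.0
protocol: {}
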