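# Dark-adaptation phantom: light-adapted baseline geometry with the default
# kinetics (linear ramp to saturation at 30 min).
scenario: dark_adaptation
model: {}          # retina_layer_model() defaults
kinetics: {}       # kinetics_params() defaults
protocol: {}       # acquisition_protocol() defaults (4 x 600 x 600, 16 fps)
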