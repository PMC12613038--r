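condition: young_epb
beta: 0.026
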