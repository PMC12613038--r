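# Aged EPB-rich condition; overrides the preset learning rate with a
# calibrated value.  Note: quote the neuron-count key ('N') if you
# override it -- YAML 1.1 reads a bare N as a boolean.
condition: aged_epb
beta: 0.045
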