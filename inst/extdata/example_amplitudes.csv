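Well,Ch1 Amplitude,Ch2 Amplitude
A01,7980.2,8112.5
A01,1034.7,7895.1
A01,8203.9,1011.4
A01,985.2,1040.8
A02,1011.0,8077.3
A02,7855.6,7944.0
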