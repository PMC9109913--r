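chr2	152433600	152433660	0.223
chr2	152340900	152340960	0.001
chr2	152465700	152465760	-0.002
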