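wavelength_um	weight
0.500	0.25
0.510	0.35
0.530	0.25
0.555	0.15
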