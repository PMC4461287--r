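gene	initial	final
g01	1	0
g02	0	1
g03	0	1
g04	1	0
g05	0	1
g06	0	1
g07	0	1
g08	0	1
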