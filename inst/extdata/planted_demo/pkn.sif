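g03	inhibit	g01
g03	activate	g02
g03	activate	g06
g04	activate	g01
g04	activate	g07
g05	activate	g06
g05	activate	g07
g05	activate	g08
g07	inhibit	g01
g07	activate	g03
g08	activate	g02
g08	activate	g08
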