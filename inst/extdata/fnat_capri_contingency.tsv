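fnat_class	High	Medium	Acceptable	Incorrect
High	204	298	148	4
Medium	0	21	106	23
Acceptable	0	0	44	547
Incorrect	0	0	0	7069
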