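# Fragment set for the reduced core network (skeleton ions, no derivative).
fragment	species	carbons	derivative_formula
Pyr123	Pyr	1-3	-
Lac123	Lac	1-3	-
Cit123456	Cit	1-6	-
Glu12345	Glu	1-5	-
Mal1234	Mal	1-4	-
Suc1234	Suc	1-4	-
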