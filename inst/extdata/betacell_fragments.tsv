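# Stand-in set of 21 GC-MS fragment ions (Mox-TBDMS derivatives of organic
# and amino acids; DiO derivative of glucose). `carbons` is the skeleton
# carbon subset retained in the ion; `derivative_formula` lists the atoms
# added by derivatization, used for natural-abundance convolution.
fragment	species	carbons	derivative_formula
Pyr123	Pyr	1-3	C6H12NOSi
Lac123	Lac	1-3	C10H25O2Si2
Lac23	Lac	2-3	C9H21OSi2
Ala123	Ala	1-3	C10H26NSi2
Ala23	Ala	2-3	C8H20NSi
Ser123	Ser	1-3	C13H32NOSi2
Ser23	Ser	2-3	C12H30NSi2
Gly12	Gly	1-2	C8H20NSi
Asp12	Asp	1-2	C12H28NO2Si2
Asp234	Asp	2-4	C13H30NO2Si2
Asp1234	Asp	1-4	C14H32NO3Si2
Glu12345	Glu	1-5	C14H32NO3Si2
Glu2345	Glu	2-5	C13H30NO2Si2
Gln12345	Gln	1-5	C14H33N2O2Si2
Cit123456	Cit	1-6	C14H31O4Si2
Mal1234	Mal	1-4	C13H29O3Si2
Mal123	Mal	1-3	C12H27O2Si2
Suc1234	Suc	1-4	C12H27O2Si2
Glyc123	Glyc	1-3	C12H29O2Si2
G3P123	G3P	1-3	C12H30O4PSi2
Glc123456	Glc.ext	1-6	C9H13O5
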