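# Reduced oxidative core network (lumped glycolysis + citric acid cycle +
# glutamine anaplerosis) used for fast simulation studies. Succinate is
# rotationally symmetric.
id	equation	reversible	role
GLY	Glc.ext (abcdef) -> Pyr (cba) + Pyr (def)	FALSE	uptake
LDH	Pyr (abc) -> Lac (abc)	FALSE	internal
LACR	Lac (abc) -> Lac.ext (abc)	FALSE	release
PYRR	Pyr (abc) -> Pyr.ext (abc)	FALSE	release
PDH	Pyr (abc) -> CO2 (a) + AcCoA (bc)	FALSE	internal
PC	Pyr (abc) + CO2 (d) -> OAA (abcd)	FALSE	internal
CS	OAA (abcd) + AcCoA (ef) -> Cit (dcbfea)	FALSE	internal
IDH	Cit (abcdef) -> AKG (abcde) + CO2 (f)	TRUE	internal
AKGDH	AKG (abcde) -> CO2 (a) + Suc (bcde)	FALSE	internal
SDH	Suc (abcd) -> Mal (abcd)	FALSE	internal
MDH	Mal (abcd) -> OAA (abcd)	TRUE	internal
ME	Mal (abcd) -> Pyr (abc) + CO2 (d)	FALSE	internal
GLNU	Gln.ext (abcde) -> Glu (abcde)	FALSE	uptake
GDH	Glu (abcde) -> AKG (abcde)	TRUE	internal
CITR	Cit (abcdef) -> Cit.ext (abcdef)	FALSE	release
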