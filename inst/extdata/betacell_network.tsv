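# Oxidative beta-cell (betaTC3-like) reaction network with carbon atom maps.
# Glycolysis, oxidative PPP with transketolase/transaldolase return,
# serine/glycine branch, glycerol release via G3P phosphatase, pyruvate
# node (LDH/ALT/PDH/PC/ME), citric acid cycle with reversible IDH
# (reductive carboxylation), glutamine anaplerosis, and medium exchanges.
# Succinate and fumarate are rotationally symmetric (50/50 scrambling).
# CO2 is an unbalanced natural-abundance pool by default.
id	equation	reversible	role
GK	Glc.ext (abcdef) -> G6P (abcdef)	FALSE	uptake
PGI	G6P (abcdef) -> F6P (abcdef)	FALSE	internal
G6PDH	G6P (abcdef) -> CO2 (a) + P5P (bcdef)	FALSE	internal
TKT1	P5P (abcde) + P5P (fghij) -> S7P (abfghij) + GAP (cde)	FALSE	internal
TALA	S7P (abcdefg) + GAP (hij) -> F6P (abchij) + E4P (defg)	FALSE	internal
TKT2	P5P (abcde) + E4P (fghi) -> F6P (abfghi) + GAP (cde)	FALSE	internal
ALD	F6P (abcdef) -> DHAP (cba) + GAP (def)	FALSE	internal
TPI	DHAP (abc) -> GAP (cba)	FALSE	internal
GAPD	GAP (abc) -> PG3 (abc)	FALSE	internal
PK	PG3 (abc) -> Pyr (abc)	FALSE	internal
PSP	PG3 (abc) -> Ser (abc)	FALSE	internal
SHMT	Ser (abc) -> Gly (ab) + C1U (c)	FALSE	internal
GPD	DHAP (abc) -> G3P (abc)	FALSE	internal
G3PP	G3P (abc) -> Glyc (abc)	FALSE	internal
LDH	Pyr (abc) -> Lac (abc)	FALSE	internal
ALT	Pyr (abc) -> Ala (abc)	FALSE	internal
PDH	Pyr (abc) -> CO2 (a) + AcCoA (bc)	FALSE	internal
PC	Pyr (abc) + CO2 (d) -> OAA (abcd)	FALSE	internal
ME	Mal (abcd) -> Pyr (abc) + CO2 (d)	FALSE	internal
CS	OAA (abcd) + AcCoA (ef) -> Cit (dcbfea)	FALSE	internal
IDH	Cit (abcdef) -> AKG (abcde) + CO2 (f)	TRUE	internal
AKGDH	AKG (abcde) -> CO2 (a) + Suc (bcde)	FALSE	internal
SDH	Suc (abcd) -> Fum (abcd)	FALSE	internal
FUM	Fum (abcd) -> Mal (abcd)	FALSE	internal
MDH	Mal (abcd) -> OAA (abcd)	TRUE	internal
AAT	OAA (abcd) -> Asp (abcd)	FALSE	internal
GLNU	Gln.ext (abcde) -> Gln (abcde)	FALSE	uptake
GLS	Gln (abcde) -> Glu (abcde)	FALSE	internal
GDH	Glu (abcde) -> AKG (abcde)	TRUE	internal
PYRR	Pyr (abc) -> Pyr.ext (abc)	FALSE	release
LACR	Lac (abc) -> Lac.ext (abc)	FALSE	release
ALAR	Ala (abc) -> Ala.ext (abc)	FALSE	release
CITR	Cit (abcdef) -> Cit.ext (abcdef)	FALSE	release
GLUR	Glu (abcde) -> Glu.ext (abcde)	FALSE	release
SERR	Ser (abc) -> Ser.ext (abc)	FALSE	release
GLYR	Gly (ab) -> Gly.ext (ab)	FALSE	release
C1R	C1U (a) -> C1.ext (a)	FALSE	release
GLYCR	Glyc (abc) -> Glyc.ext (abc)	FALSE	release
MALR	Mal (abcd) -> Mal.ext (abcd)	FALSE	release
SUCR	Suc (abcd) -> Suc.ext (abcd)	FALSE	release
ASPR	Asp (abcd) -> Asp.ext (abcd)	FALSE	release
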