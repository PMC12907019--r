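family	superfamily	group	role	ignored
MER31B	ERV1	MER31	LTR	0
MER31-int	ERV1	MER31	internal	0
LOR1a	ERV1	LOR1	LTR	0
LOR1-int	ERV1	LOR1	internal	0
HERVE-int	ERV1	HERVE	internal	0
LTR2	ERV1	HERVE	LTR	0
HERVK-int	ERV2	HML2	internal	0
LTR5_Hs	ERV2	HML2	LTR	0
THE1A	ERV3	MaLR	LTR	0
THE1A-int	ERV3	MaLR	internal	0
THE1B	ERV3	MaLR	LTR	0
MLT1J	ERV3	MaLR	LTR	0
MLT1K	ERV3	MaLR	LTR	0
HERVL-int	ERV3	HERVL	internal	0
MLT2A1	ERV3	HERVL	LTR	0
HERVS71-int	ERV3	HERVS	internal	0
LTR6A	ERV3	HERVS	LTR	0
MamGyp-int	Gypsy	MamGyp	internal	0
MamGypLTR1a	Gypsy	MamGyp	LTR	0
ERV-uncl-1	Unclassified	Unclassified	LTR	0
ERV-uncl-2	Unclassified	Unclassified	internal	0
ORPHAN-int-1	ERV1	MER31	internal	1
ORPHAN-LTR-1	ERV3	MaLR	LTR	1
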