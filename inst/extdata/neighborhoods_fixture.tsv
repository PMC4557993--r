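# Fixture gene neighborhoods built from the published gene-context lists.
# bovine_chr18: bovine-style BSP pattern (BSP1/BSP3/BSP5, fully consistent)
# ovine_chr14_bsph: BSPH1/BSPH2 with ELSPBP1
# mouse_bsph: BSPH1/BSPH2 without ELSPBP1 (PLA2G4C present)
# ferret_GL897027_like: ELSPBP1 context where the BSPH1-labelled gene has a
#   BSPH2 sequence call (misannotation case)
scaffold_id	species	source	rank	symbol	strand	call
bovine_chr18	Bos taurus	fixture	1	CD177	+
bovine_chr18	Bos taurus	fixture	2	TEX101	+
bovine_chr18	Bos taurus	fixture	3	BSP5	+	BSP
bovine_chr18	Bos taurus	fixture	4	BSP3	+	BSP
bovine_chr18	Bos taurus	fixture	5	BSP1	+	BSP
bovine_chr18	Bos taurus	fixture	6	LYPD3	+
bovine_chr18	Bos taurus	fixture	7	PHLDB3	+
bovine_chr18	Bos taurus	fixture	8	ETHE1	+
bovine_chr18	Bos taurus	fixture	9	ZNF575	+
ovine_chr14_bsph	Ovis aries	fixture	1	C19orf68	+
ovine_chr14_bsph	Ovis aries	fixture	2	LIG1	+
ovine_chr14_bsph	Ovis aries	fixture	3	CABP5	+
ovine_chr14_bsph	Ovis aries	fixture	4	ELSPBP1	+
ovine_chr14_bsph	Ovis aries	fixture	5	BSPH1	+	BSPH1
ovine_chr14_bsph	Ovis aries	fixture	6	BSPH2	+	BSPH2
ovine_chr14_bsph	Ovis aries	fixture	7	SULT2A1	+
ovine_chr14_bsph	Ovis aries	fixture	8	CRX	+
mouse_bsph	Mus musculus	fixture	1	PLA2G4C	+
mouse_bsph	Mus musculus	fixture	2	BSPH2	+	BSPH2
mouse_bsph	Mus musculus	fixture	3	BSPH1	+	BSPH1
mouse_bsph	Mus musculus	fixture	4	SULT2A1	+
mouse_bsph	Mus musculus	fixture	5	CRX	+
ferret_GL897027_like	Mustela putorius furo	fixture	1	C19orf68	+
ferret_GL897027_like	Mustela putorius furo	fixture	2	LIG1	+
ferret_GL897027_like	Mustela putorius furo	fixture	3	CABP5	+
ferret_GL897027_like	Mustela putorius furo	fixture	4	ELSPBP1	+
ferret_GL897027_like	Mustela putorius furo	fixture	5	BSPH1	+	BSPH2
ferret_GL897027_like	Mustela putorius furo	fixture	6	SULT2A1	+
ferret_GL897027_like	Mustela putorius furo	fixture	7	CRX	+
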