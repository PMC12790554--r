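catalog	name	smarts	example_hit	example_miss
PAINS	quinone_A	[OX1]=[#6]1[#6]=[#6][#6](=[OX1])[#6]=[#6]1	O=C1C=CC(=O)C=C1	Oc1ccccc1
PAINS	azo_aryl	[cX3][NX2]=[NX2][cX3]	c1ccc(cc1)N=Nc1ccccc1	Nc1ccccc1
PAINS	rhodanine_core	[SX2]1[CX3](=[SX1])[NX3][CX3](=[OX1])[CX4]1	S=C1NC(=O)CS1	O=C1NC(=O)CS1
PAINS	hydrazone_A	[CX3]=[NX2][NX3]	CC=NN	CC=NC
PAINS	catechol_A	[cX3]([OX2H])[cX3][OX2H]	Oc1ccccc1O	Oc1ccccc1
Brenk	thiol	[SX2H]	CCS	CSC
Brenk	hydrazine	[NX3][NX3]	NNc1ccccc1	Nc1ccccc1
Brenk	azide	[NX2]~[NX2+]~[NX1-]	CCN=[N+]=[N-]	CCN
Brenk	disulfide	[SX2][SX2]	CSSC	CSC
Brenk	peroxide	[OX2][OX2]	COOC	COC
Brenk	thiocarbonyl	[CX3]=[SX1]	CC(N)=S	CC(N)=O
Brenk	alkyl_br_i	[CX4][Br,I]	CCBr	c1ccc(cc1)Br
Brenk	quaternary_n	[NX4+]	C[N+](C)(C)C	CN(C)C
NIH	acyl_hydrazine	[CX3](=[OX1])[NX3][NX3]	CC(=O)NN	CC(=O)N
NIH	beta_lactam	[NX3]1[CX3](=[OX1])[CX4][CX4]1	O=C1CCN1	O=C1CCCN1
ZINC	thiourea	[NX3][CX3](=[SX1])[NX3]	NC(=S)N	NC(=O)N
ZINC	enol_ether	[CX3]=[CX3][OX2][#6]	C=COC	CCOC
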