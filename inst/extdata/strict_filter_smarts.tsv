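rule_class	name	smarts	example_hit	example_miss
promoiety	ester	[CX3](=[OX1])[OX2H0][#6]	CCOC(C)=O	CCO
promoiety	carbonate	[#6][OX2][CX3](=[OX1])[OX2][#6]	COC(=O)OC	CCOC(C)=O
promoiety	carbamate	[NX3][CX3](=[OX1])[OX2H0]	CNC(=O)OC	CC(=O)NC
promoiety	phosphate_ester	[#6][OX2][PX4]=[OX1]	COP(=O)(O)O	CP(=O)(O)O
promoiety	phosphonate_ester	[#6][PX4](=[OX1])[OX2][#6]	CP(=O)(OC)OC	COP(=O)(O)O
promoiety	sulfate_ester	[#6][OX2][SX4](=[OX1])=[OX1]	COS(=O)(=O)O	CS(=O)(=O)O
promoiety	azo	[#6][NX2]=[NX2][#6]	c1ccc(cc1)N=Nc1ccccc1	CC=NC
promoiety	nitro	[#7X3](~[OX1])~[OX1]	c1ccc(cc1)[N+](=O)[O-]	Nc1ccccc1
promoiety	nitroso	[NX2]=[OX1]	O=Nc1ccccc1	c1ccc(cc1)[N+](=O)[O-]
promoiety	quinone_imine	[OX1]=[#6]1[#6]=[#6][#6](=[NX2])[#6]=[#6]1	N=C1C=CC(=O)C=C1	O=C1C=CC(=O)C=C1
promoiety	catechol_like	[cX3]([OX2H])[cX3][OX2H]	Oc1ccccc1O	Oc1ccccc1
warhead	aldehyde	[CX3H1]=[OX1]	CC=O	CC(C)=O
warhead	acyl_halide	[CX3](=[OX1])[F,Cl,Br,I]	CC(=O)Cl	CC(=O)O
warhead	anhydride	[CX3](=[OX1])[OX2][CX3]=[OX1]	CC(=O)OC(C)=O	CCOC(C)=O
warhead	isocyanate	[NX2]=[CX2]=[OX1]	CN=C=O	CNC(=O)OC
warhead	epoxide	[CX4]1[OX2][CX4]1	CC1CO1	C1CCO1
warhead	aziridine	[CX4]1[NX3][CX4]1	C1CN1	C1CCN1
warhead	michael_acceptor	[CX3]=[CX3][CX3]=[OX1]	C=CC(C)=O	CC(C)=O
warhead	vinyl_sulfone	[CX3]=[CX3][SX4](=[OX1])=[OX1]	C=CS(C)(=O)=O	CCS(C)(=O)=O
warhead	chloroacetamide	Cl[CX4][CX3](=[OX1])[NX3]	ClCC(=O)NC	CC(=O)NC
warhead	sulfonyl_chloride	[SX4](=[OX1])(=[OX1])Cl	CS(=O)(=O)Cl	CS(=O)(=O)O
warhead	imine	[CX3]=[NX2][#6]	CC=NC	CCNC
warhead	oxime	[CX3]=[NX2][OX2H]	CC(C)=NO	CC=NC
warhead	hydroxamic_acid	[CX3](=[OX1])[NX3][OX2H]	CC(=O)NO	CC(=O)N
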