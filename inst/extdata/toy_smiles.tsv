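set	name	smiles	expected_rules
promoiety	ethyl_acetate	CCOC(C)=O	promoiety:ester
promoiety	dimethyl_carbonate	COC(=O)OC	promoiety:ester,promoiety:carbonate
promoiety	methyl_methylcarbamate	CNC(=O)OC	promoiety:ester,promoiety:carbamate
promoiety	methyl_phosphate	COP(=O)(O)O	promoiety:phosphate_ester
promoiety	dimethyl_methylphosphonate	CP(=O)(OC)OC	promoiety:phosphate_ester,promoiety:phosphonate_ester
promoiety	methyl_sulfate	COS(=O)(=O)O	promoiety:sulfate_ester
promoiety	azobenzene	c1ccc(cc1)N=Nc1ccccc1	promoiety:azo,alert:PAINS
promoiety	nitrobenzene	c1ccc(cc1)[N+](=O)[O-]	promoiety:nitro
promoiety	nitrosobenzene	O=Nc1ccccc1	promoiety:nitroso
promoiety	quinone_imine	N=C1C=CC(=O)C=C1	promoiety:quinone_imine,warhead:michael_acceptor
promoiety	catechol	Oc1ccccc1O	promoiety:catechol_like,alert:PAINS
warhead	acetaldehyde	CC=O	warhead:aldehyde
warhead	acetyl_chloride	CC(=O)Cl	warhead:acyl_halide
warhead	acetic_anhydride	CC(=O)OC(C)=O	promoiety:ester,warhead:anhydride
warhead	methyl_isocyanate	CN=C=O	warhead:isocyanate
warhead	propylene_oxide	CC1CO1	warhead:epoxide
warhead	aziridine	C1CN1	warhead:aziridine
warhead	methyl_vinyl_ketone	C=CC(C)=O	warhead:michael_acceptor
warhead	methyl_vinyl_sulfone	C=CS(C)(=O)=O	warhead:vinyl_sulfone
warhead	n_methyl_chloroacetamide	ClCC(=O)NC	warhead:chloroacetamide
warhead	mesyl_chloride	CS(=O)(=O)Cl	warhead:sulfonyl_chloride
warhead	n_methyl_ethanimine	CC=NC	warhead:imine
warhead	acetone_oxime	CC(C)=NO	warhead:oxime
warhead	acetohydroxamic_acid	CC(=O)NO	warhead:hydroxamic_acid
passer	benzene	c1ccccc1	
passer	ibuprofen	CC(C)Cc1ccc(cc1)C(C)C(=O)O	
passer	pyridine	c1ccncc1	
passer	triethylamine	CCN(CC)CC	
passer	o_xylene	Cc1ccccc1C	
passer	hydroxyethyl_piperidine	OCCN1CCCCC1	
window	tetracontane	CCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC	window:mw,window:clogp,window:rotb
window	edta	OC(=O)CN(CCN(CC(=O)O)CC(=O)O)CC(=O)O	window:clogp,window:tpsa,window:rotb
window	disaccharide	OCC1OC(OC2C(O)C(O)C(O)OC2CO)C(O)C(O)C1O	window:hbd,window:hba,window:clogp,window:tpsa
window	tetradecane	CCCCCCCCCCCCCC	window:clogp,window:rotb
element	diethyl_selenide	CC[Se]CC	element_whitelist
stereo_pair	l_alanine	C[C@H](N)C(=O)O	
stereo_pair	d_alanine	C[C@@H](N)C(=O)O	
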