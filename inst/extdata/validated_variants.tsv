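patient_id	gene	variant	vaf
100	FGF14	p.Thr224Met	0.26
100	MAPK8IP3	p.Val1314fs	0.21
100	RPS6KA1	p.Ser430fs	0.4
115	PIK3R1	p.Ser565_Ile566insGluTyrArgGluIleAspLysArgMetAsnSer	0.38
115	TAOK2	p.Val244Met	0.25
115	TNFRSF1A	p.Pro102Arg	0.34
117	TMEM127	p.His165Arg	0.12
165	DDX3X	c.104-2A>G	0.89
165	TET2	p.Arg1465*	0.31
165	RXRG	c.623-1G>C	0.22
165	CFH	p.Gly1118Glu	0.37
165	MPZL1	p.Phe60Leu	0.34
165	EFEMP1	p.Arg362*	0.40
165	SALL1	p.Ala377fs	0.48
187	RSF1	p.Val68Met	0.43
260	SETD1B	p.Ala889Asp	0.14
452	MAP10	p.Leu846*	0.23
452	PAXIP1	p.Gly638Ser	0.25
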