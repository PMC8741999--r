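patient_id	gene	transcript	cdna	protein	consequence	zygosity	dbsnp	phenotype	segregation	reference	clinvar	after_curation	criteria
1	CDH23	NM_022124.5	c.337del	p.(Val113*)	nonsense	het		Usher syndrome. PL, PR, B, PF, CI	Maternal	This work		Pathogenic	PM2, PVS1, PM3, PP4
1	CDH23	NM_022124.5	c.3353del	p.(Gly1118Alafs*7)	frameshift	het		Usher syndrome. PL, PR, B, PF, CI	Paternal	This work		Pathogenic	PM2, PVS1, PM3, PP4
2	MYO6	NM_004999.4	c.1939T>C	p.(Phe647Leu)	missense	het	rs752585373	PL, B, M	Non available	This work		VUS	PM2, PP3
3	EYA4	NM_004100.5	c.580+2T>C		splice_site	het		PL, B, M	Maternal	This work		Pathogenic	PM2, PVS1, PP1_Sup
4	MYO7A	NM_000260.4	c.733C>T	p.(Gln245*)	nonsense	het		C, PL, B, PF, CI	Maternal	This work		Pathogenic	PVS1, PM2, PM3
4	MYO7A	NM_000260.4	c.1344-2A>G		splice_site	het	rs111033415	C, PL, B, PF, CI	Paternal	Ref65	Pathogenic	Pathogenic	PM2, PVS1, PM3_S, PP4
5	LARS2	NM_015340.3	c.1481dup	p.(Leu495Thrfs*31)	frameshift	het	rs762797278	C, B, PF, CI	Paternal	This work		Pathogenic	PVS1, PM2, PM3, PP1_Sup
5	LARS2	NM_015340.3	c.1886C>T	p.Thr629Met	missense	het	rs398123036	C, B, PF, CI	Maternal	Ref16	Pathogenic	Likely Pathogenic	PM2, PM3_S, PP1_Sup, PP4
6	ADGRV1	NM_032119.3	c.12829C>T	p.(Arg4277*)	nonsense	het		Usher syndrome. B, P, PR	Non available father	This work		Pathogenic	PVS1, PM2, PM3, PP1_Sup, PP4
6	ADGRV1	NM_032119.3	c.956dup	p.(Asn319Lysfs*6)	frameshift	het	rs752179149	Usher syndrome. B, P, PR	Maternal	Ref66	Pathogenic	Pathogenic	PVS1, PM2, PM3, PP1_Sup, PP4
7	MITF	NM_000248.3	c.877C>T	p.(Arg293*)	nonsense	het		C, B, PF, CI	Segregation confirmed	Ref15		Pathogenic	PM2, PVS1_S, PP1_S
8	TMPRSS3	NM_024022.3	c.1276G>A	p.Ala426Thr	missense	het	rs56264519	PL, B, sloping audiometry	Maternal inheritance	Ref67	Pathogenic/Likely Path	Pathogenic	BS1_Sup, PM3_VS, PP1_S, PS3_Sup
8	TMPRSS3	NM_024022.3	c.242C>G	p.(Ser81*)	nonsense	het	rs757110501	PL, B, sloping audiometry	Paternal inheritance	This work		Pathogenic	PVS1, PM2, PM3, PP1_Sup
9	WFS1	NM_006005.3	c.2590G>A	p.(Glu864Lys)	missense	het	rs74315205	B, CI		Ref68	Pathogenic/Likely Path	Likely Pathogenic	PM2, PS4_M, PP1_Mod, PP3
10	USH2A	NM_206933.4	c.1841-2A>G		splice_site	het	rs397518003	PR, B, M. No retinopathies	Maternal inheritance	Ref69	Pathogenic	Pathogenic	PM2, PM3_VS, PP4, PP1_M, PS3_S
10	USH2A	NM_206933.4	c.10712C>T	p.(Thr3571Met)	missense	het	rs202175091	PR, B, M. No retinopathies	Paternal inheritance	Ref70	Pathogenic/Likely Path	Pathogenic	PM2, PM3_VS, PP4, PP1_M
11	CDH23	NM_022124.5	c.1096G>A	p.(Ala366Thr)	missense	het	rs143282422	B, high-frequency affected. No retinopathies	Maternal	Ref71	Benign	Benign	BA1
11	CDH23	NM_022124.5	c.1515-12G>A		splice_site	het	rs369396703	B, high-frequency affected. No retinopathies	Paternal		VUS (validated by HL-EP)	Likely Pathogenic	PM2_Sup, PM3, PP1_Sup, PP3, PP4
12	COL4A3	NM_000091.5	c.3500G>A	p.(Gly1167Glu)	missense	het		Alport syndrome. Hematuria	De novo (maternal)	This work		Pathogenic	PM2, PS2, PM1, PM5, PP3
12	COL4A3	NM_000091.5	c.4649T>G	p.(Val1550Gly)	missense	het	rs200655479	Alport syndrome. Hematuria		Ref72	Conflicting Interpretation (VUS/LP)	VUS	PM2_Sup, PP3
13	DFNA5	NM_004403.2	c.119dup	p.(Lys41Glufs*113)	frameshift	het	rs758488919	No familial history	De novo		Conflicting Interpretation (VUS/LB)	Benign	BA1, PS2
14	COL4A5	NM_000495.3	c.1183C>T	p.(Pro395Ser)	missense	het		C, B, S		This work		VUS	PM2
15	COL4A5	NM_000495.3	c.1759C>T	p.(Pro587Ser)	missense	het		PL, PR, B, M		This work		VUS	PM2, PP3
16	COL4A5	NM_000495.3	c.3659G>A	p.(Gly1220Asp)	missense	het	rs104886251	Alport syndrome. Hematuria		Ref73	Pathogenic	Pathogenic	PM2, PM1, PP3, PP4, PS4_Sup
17	WFS1	NM_006005.3	c.2327A>T	p.(Glu776Val)	missense	het	rs56002719	B, M, PR. High frequencies	Maternal inheritance	Ref74	Conflicting Interpretation (VUS/B/LB)	Benign	BA1, PP3, PP1_Sup, BS4
18	TECTA	NM_005422.4	c.5668C>T	p.(Arg1890Cys)	missense	het	rs121909063	PL, M-S	Segregation confirmed. Paternal inheritance	Ref75	Likely pathogenic	Pathogenic	PM2, PP1_VS, PS4_Sup
19	LOXHD1	NM_144612.6	c.4480C>T	p.(Arg1494*)	nonsense	hom	rs201587138	C, B, PF	Segregation confirmed	Ref76	Pathogenic/Likely Path	Pathogenic	PVS1, BS1_Sup, PM3_S, PP1_M
20	ACTG1	NM_001614.5	c.353A>T	p.(Lys118Met)	missense	het	rs104894544	PL, B, M-S	Segregation confirmed. Paternal inheritance	Ref77	Likely pathogenic	Pathogenic	PS4_Sup, PM2, PP5, PP1_S, PP3
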