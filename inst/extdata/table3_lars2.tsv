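cdna	protein	consequence	effect	effect_label	ddg_mean	ddg_sd	clinvar	dvd_lovd	classification	criteria	reference	in_interface	in_helix	buried
c.351G>C	p.(Met117Ile)	missense	Stability	stability	4.11	0.63		P/LP	Likely Pathogenic	PM2, PM3, PP1, PP4, PP3	PMID:26970254	FALSE	FALSE	TRUE
c.371A>T	p.(Asn124Ile)	missense	Non conclusive	nonconclusive	0.41	0.66	P	P/-	Likely Pathogenic	PM2, PM3_Strong, PP4	PMID:28708303	FALSE	FALSE	FALSE
c.440A>C	p.(Gln147Pro)	missense	Stability	stability	1.49	0.12	LP	LP/-	Likely Pathogenic	PM2, PM3, PP4, BP4_Supporting, PP3	SCV000994657.1	FALSE	TRUE	FALSE
c.457A>C	p.(Asn153His)	missense	Stability	stability	3.36	0.82	LP	LP/-	Likely Pathogenic	PM2, PM3, PP3, PP4	PMID:32423379	FALSE	TRUE	FALSE
c.683G>A	p.(Arg228His)	missense	Electrostatic Surface	electrostatic_surface	0.40	0.02	LP	LP/LP	Likely Pathogenic	PM2, PM3_Supporting, PP3, PP4	PMID:28000701	FALSE	FALSE	FALSE
c.880G>A	p.(Glu294Lys)	missense	Electrostatic surface	electrostatic_surface	0.67	0.14		P/LP	Likely Pathogenic	PM2, PM3_Strong, PP4, PP3	PMID:28000701	FALSE	FALSE	FALSE
c.899C>T	p.(Thr300Met)	missense	tRNA interaction	interface_interaction	0.12	0.84	P	P/P	Likely Pathogenic	PM2, PM3, PP1, PP3, PP4	PMID:26657938	TRUE	FALSE	FALSE
c.1077del	p.Ile360fs	frameshift	LoF	LoF			P	P/P	Pathogenic	PVS1, PS3_Supporting, PM2, PM3, PP4	PMID:23541342	FALSE	FALSE	FALSE
c.1115C>G	p.(Ser372*)	nonsense	LoF	LoF			LP	LP/-	Pathogenic	PVS1, PM2, PP4	SCV000891207.1	FALSE	FALSE	FALSE
c.1237G>A	p.(Glu413Lys)	missense	Electrostatic surface	electrostatic_surface	0.14	0.02	LP	LP/-	VUS	PM2, BP4, PP4	SCV001244305.1	FALSE	FALSE	FALSE
c.1358G>A	p.(Arg453Gln)	missense	Electrostatic surface/Stability?	nonconclusive	1.42	0.3		P/P	Likely Pathogenic	PM2_Supporting, PM3, PP3, PP4	PMID:27650058	FALSE	FALSE	TRUE
c.1481dup	p.(Leu495fs)	frameshift	LoF	LoF			-	P/-	Pathogenic	PVS1, PM2, PM3, PP1_Supporting	This study	FALSE	FALSE	FALSE
c.1520C>G	p.(Pro507Arg)	missense	Stability	stability	2.20	0.07	LP	LP/-	Likely Pathogenic	PM2, PM3, PP1_Supporting, PP3	SCV000731430.1	FALSE	FALSE	TRUE
c.1556C>T	p.(Thr519Met)	missense	Steric (core)	nonconclusive	-0.44	0.25		P/-	Likely Pathogenic	PM2, PM3, PP1_Supporting, PP3, PP4	PMID:29205794	FALSE	FALSE	TRUE
c.1565C>A	p.Thr522Asn	missense	Steric (core)	nonconclusive	-0.59	0.08	LP	P/LP	Likely Pathogenic	PM2_Supporting, PM3_Strong, PS3_Supporting, PP3, PP4	PMID:23541342	FALSE	FALSE	TRUE
c.1607C>T	p.(Pro536Leu)	missense	Stability	stability	6.82	1.87	LP	LP/-	Likely Pathogenic	PM2, PS3_Supporting, PM3, PP3, PP4	SCV000994658.1	FALSE	TRUE	FALSE
c.1886C>T	p.Thr629Met	missense	Stability	stability	2.56	0.19	P	P/P	Likely Pathogenic	PM2, PM3_Strong, PP1_Sup, PP4	PMID:23541342	FALSE	FALSE	FALSE
c.1912G>A	p.(Glu638Lys)	missense	tRNA interaction	interface_interaction	-0.06	0.50	P	P/P	Likely Pathogenic	PM2, PM3, PP1_Supporting, PP3, PP4	PMID:26657938	TRUE	FALSE	FALSE
c.1987C>T	p.(Arg663Trp)	missense	Stability	stability	2.94	0.32	P	P/-	Likely Pathogenic	PM2, PS3_Supporting, PM3_Strong, PP3, PP4	PMID:28708303	FALSE	FALSE	TRUE
c.2108T>C	p.(Ile703Thr)	missense	tRNA interaction	interface_interaction	0.67	0.11		LP/-	Likely Pathogenic	PM2, PM3, PP3, PP4	PMID:32767731	TRUE	FALSE	FALSE
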