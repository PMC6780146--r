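peptide_id	sequence	activity_um	source
A01	IPP	5.0	beta-casein (fermented milk)
A02	VPP	9.0	beta-casein (fermented milk)
A03	LKP	0.32	dried bonito muscle
A04	IKP	1.7	dried bonito muscle
A05	LRP	0.27	bonito protein hydrolysate
A06	LRW	0.21	plant protein hydrolysate
A07	GLP	1.5	fish muscle hydrolysate
A08	LGP	0.72	fish muscle hydrolysate
A09	VSV	1.9	muscle protein hydrolysate
A10	KGYGGVSLPEW	0.83	whole whey proteins
A11	IW	0.7	sake and sake lees
A12	VW	1.4	sake and sake lees
A13	AW	10	marine protein hydrolysate
A14	LW	23.6	plant protein hydrolysate
A15	KW	0.21	fish protein hydrolysate
A16	IY	3.7	sake and sake lees
A17	VY	7.1	sardine muscle
A18	FY	3.4	sardine muscle
A19	AY	14.2	dried bonito
A20	GY	210	rice protein
A21	RY	10.5	rice protein
A22	YP	720	fermented milk
A23	IVY	0.48	wheat germ hydrolysate
A24	IPA	141	beta-lactoglobulin
A25	GPL	2.55	bovine skin gelatin
A26	GPV	4.7	bovine skin gelatin
A27	VAP	2.0	alpha-casein
A28	LQP	1.9	alpha-casein
A29	IQP	1.4	spinach ribulose protein
A30	VAF	0.46	sardine muscle hydrolysate
A31	IKW	0.21	chicken muscle hydrolysate
A32	MKP	0.45	casein hydrolysate
A33	LAP	3.5	chicken muscle hydrolysate
A34	IRP	1.8	chicken muscle hydrolysate
A35	VRP	2.2	fish protein hydrolysate
A36	LPP	9.6	fermented milk
A37	LSP	1.7	fermented grain
A38	LVL	29	soy protein hydrolysate
A39	AFL	63.8	soy protein hydrolysate
A40	GVP	252	gelatin hydrolysate
A41	IYP	8.1	wheat gluten hydrolysate
A42	TAP	18	casein hydrolysate
A43	VKP	1.3	fish protein hydrolysate
A44	GKP	3.5	shrimp protein hydrolysate
A45	VTP	10	fermented milk
A46	HLP	5.7	collagen hydrolysate
A47	GIP	14	gelatin hydrolysate
A48	LNP	82	fish muscle hydrolysate
A49	LKPNM	2.4	dried bonito muscle
A50	IWHHT	5.8	dried bonito muscle
A51	IPAVF	44.8	beta-lactoglobulin
A52	LHLPLP	3.2	beta-casein
A53	TTMPLW	16	alpha-casein
A54	VLPVPQ	5.8	beta-casein
A55	ALPMHIR	42.6	beta-lactoglobulin
A56	AVPYPQR	15	beta-casein
A57	RADHPFL	6.2	egg white ovalbumin
A58	YAEERYPIL	4.67	egg white ovalbumin
A59	FFVAPFPEVFGK	77	alpha-casein
A60	DLTDY	98	marine algae protein
X01	GPRP	NA	synthetic control peptide
X02	PLW	NA	uncharacterised hydrolysate fraction
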