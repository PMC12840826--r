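# Benchmark fixture: 37 VGSC variants observed across five Hainan populations
# of Liriomyza trifolii (MY, TS, DA, TY, JY).  Per population: f = observations
# without the nucleotide change, g = observations with it, pct = recorded
# display frequency 100*g/(f+g) at 2 dp.  Empty cells = variant not detected.
# Known errata (recorded value inconsistent with its own counts; counts are
# authoritative): Y866Y/TY recorded 22.23, recomputed 22.22.
# V1845I: the alternate codon is recorded as ATT, the single-base change
# (G>A at codon offset 0) yielding the V->I substitution; survey reports of
# this site sometimes print the two-base codon variant ATA (also Ile).
region	snp	class	ref_codon	alt_codon	MY_f	MY_g	MY_pct	TS_f	TS_g	TS_pct	DA_f	DA_g	DA_pct	TY_f	TY_g	TY_pct	JY_f	JY_g	JY_pct
D I-S1	L145L	synonymous	TTA	TTG	59	16	21.33	78	10	11.36	53	8	13.11	62	12	16.22	53	8	13.11
D I-S56-L	I290I	synonymous	ATT	ATC	89	33	27.05	100	22	18.03	60	18	23.08	97	18	15.65	102	14	12.07
D I-S56-L	S319S	synonymous	TCT	TCA	82	27	24.77	72	24	25.00	50	18	26.47	81	12	12.90	86	14	14.00
D I-S56-L	Y354Y	synonymous	TAT	TAC				82	9	9.89	81	11	11.96						
D I-II-L	A470A	synonymous	GCG	GCT				64	6	8.57									
D I-II-L	L474L	synonymous	TTA	TTG				53	13	19.70	61	24	28.24				94	16	14.55
D I-II-L	E496E	synonymous	GAG	GAA	48	18	27.27	35	11	23.91	57	28	32.94	65	14	17.72	71	12	14.46
D I-II-L	E505E	synonymous	GAA	GAG	47	14	22.95	39	9	18.75	55	22	28.57	52	8	13.33	61	10	14.08
D I-II-L	E661E	synonymous	GAG	GAA	59	38	39.18	59	14	19.18	81	9	10.00	77	18	18.95			
D I-II-L	A685A	synonymous	GCC	GCA	54	43	44.33	51	17	25.00	79	10	11.24	68	18	20.93			
D I-II-L	L733L	synonymous	TTG	TTA	38	45	54.22	64	18	21.95	61	8	11.59	92	27	22.69	114	13	10.24
D I-II-L	L778L	synonymous	CTC	CTT	67	56	45.53	83	19	18.63	109	17	13.49	91	37	28.91			
D II-S1	T814T	synonymous	ACA	ACG	58	48	45.28	80	20	20.00	89	22	19.82	75	32	29.91			
D II-S23-L	Y866Y	synonymous	TAC	TAT	56	35	38.46	74	17	18.68				70	20	22.23			
D II-S5	N931N	synonymous	AAC	AAT	39	36	48.00	52	17	24.64	66	18	21.43	83	16	16.16	105	8	7.08
D II-S56-L	S978S	synonymous	TCT	TCG	41	46	52.87	54	18	25.00	79	17	17.71	82	18	18.00	119	12	9.16
D II-III-L	A1112A	synonymous	GCT	GCA	43	35	44.87	50	14	21.88	59	18	23.38	68	22	24.44	74	8	9.76
D II-III-L	L1231L	synonymous	CTA	CTT							90	12	11.76						
D II-III-L	D1232D	synonymous	GAT	GAC							86	12	12.24						
D II-III-L	P1282P	synonymous	CCT	CCG	72	40	35.71	88	23	20.72	77	31	28.70	67	25	27.17	113	15	11.72
D III-S3	F1372F	synonymous	TTT	TTC	30	6	16.67	37	3	7.50									
D III-S56-L	I1471I	synonymous	ATC	ATT				89	10	10.10									
D III-S56-L	Y1483Y	synonymous	TAT	TAC				88	17	16.19									
D IV < L	H1996H	synonymous	CAC	CAT	75	36	32.43	66	15	18.52	92	14	13.21	83	25	23.15			
D IV < L	Q2006Q	synonymous	CAA	CAG	31	81	72.32	14	57	80.28	15	86	85.15	23	76	76.77	7	116	94.31
D IV < L	R2011R	synonymous	CGA	CGT	30	78	72.22	11	52	82.54	15	87	85.29	22	73	76.84	7	109	93.97
D IV < L	G2022G	synonymous	GGT	GGC				54	6	10.00	93	6	6.06						
D IV < L	G2033G	synonymous	GGG	GGT	24	67	73.63	5	57	91.94	7	79	91.86	13	59	81.94	6	102	94.44
D IV < L	A2038A	synonymous	GCG	GCT				66	5	7.04									
D IV < L	G2040G	synonymous	GGA	GGT				66	6	8.33									
D IV < L	A2050A	synonymous	GCC	GCT	21	38	64.41	4	66	94.29	8	62	88.57	11	48	81.36	7	99	93.40
D II-S45-L	M922T	nonsynonymous	ATG	ACG	27	38	58.46	22	36	62.07	24	62	72.09	20	83	80.58	11	110	90.91
D II-S5	T933I	nonsynonymous	ACA	ATA				64	6	8.57									
D II-S6	L1018F	nonsynonymous	CTT	TTT	0	64	100.00	0	71	100.00	0	90	100.00	0	102	100.00	0	126	100.00
D II-III-L	Q1285H	nonsynonymous	CAA	CAC							18	72	80.00				4	111	96.52
D IV-S6	V1845I	nonsynonymous	GTT	ATT	99	57	36.54	14	88	86.27	18	72	80.00	18	70	79.55	4	111	96.52
D IV < L	D2036E	nonsynonymous	GAC	GAA				67	5	6.94									
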