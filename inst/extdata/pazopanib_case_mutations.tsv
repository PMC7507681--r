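gene	cdna_change	aa_change	assay_id	mutant_reads	coverage	vaf	significance_class
FGFR3	FGFR3-TACC3	NA	Panel1	NA	NA	NA	clinical
ADGRA2	c.G3010C	G1004R	Panel1	43	782	0.06	unknown
EP300	c.670C>T	Q224*	Panel1	628	969	0.65	potential
ERBB3	c.G2641C	E881Q	Panel1	155	960	0.16	unknown
FAM135B	c.1898T>A	L633*	Panel1	257	975	0.26	potential
GATA6	c.G551A	S184N	Panel1	26	338	0.08	potential
HRAS	c.A422C	Y141S	Panel1	32	662	0.05	unknown
IGF2	c.20A>C	Q7P	Panel1	94	445	0.21	unknown
KDM6A	c.2700_2724del	H848Qfs*11	Panel1	499	1026	0.49	potential
RANBP2	c.G3469C	D1157H	Panel1	123	832	0.15	unknown
TEK	c.C3251A	S1084*	Panel1	63	474	0.13	unknown
TP53	c.772G>A	E258K	Panel1	235	460	0.51	potential
ATM	c.2395G>A	A799T	WES1	13	162	0.08	confirmed_somatic
CDK6	c.378G>T	M126I	WES1	6	151	0.04	unknown
EP300	c.670C>T	Q224*	WES1	27	95	0.28	potential
FAM135B	c.1898T>A	L633*	WES1	5	144	0.04	potential
FAT3	c.6854C>A	P2285H	WES1	16	141	0.11	unknown
IGF2	c.20A>C	Q7P	WES1	12	153	0.08	unknown
KDM6A	c.2700_2724del	H900Qfs*11	WES1	46	318	0.15	potential
LIMK1	c.695G>A	R232Q	WES1	7	214	0.03	unknown
LRP1	c.9730G>A	V3244I	WES1	5	213	0.02	confirmed_somatic
TCF7L2	c.670G>A	V224I	WES1	5	198	0.03	unknown
TERT	c.1520A>T	E507V	WES1	21	348	0.06	unknown
TP53	c.772G>A	E258K	WES1	53	241	0.22	potential
ACVR1B	c.85G>A	V29I	WES2	9	218	0.04	unknown
ADGRA2	c.1883C>G	S628C	WES2	9	228	0.04	unknown
AKT3	c.432A>G	T144T	WES2	8	111	0.07	unknown
ARHGAP26	c.2155C>T	R719W	WES2	15	331	0.05	confirmed_somatic
ARID1A	c.352A>C	T118P	WES2	11	110	0.10	unknown
ARID1A	c.780_782delCTC	S261del	WES2	16	179	0.09	unknown
ARID1A	c.1040_1041insAGC	A347dup	WES2	13	154	0.08	unknown
ARID1A	c.457C>G	P153A	WES2	9	191	0.05	confirmed_somatic
ARID1B	c.832G>A	G278S	WES2	23	272	0.09	unknown
ARID1B	c.884G>A	C295Y	WES2	19	273	0.07	unknown
ARID1B	c.1437G>A	M479I	WES2	7	131	0.05	unknown
ARID1B	c.1189T>G	S397A	WES2	5	172	0.03	unknown
CDK12	c.1489G>T	A497S	WES2	11	172	0.06	unknown
CDK6	c.378G>T	M126I	WES2	8	179	0.05	unknown
CDK8	c.703C>T	H235Y	WES2	5	206	0.02	unknown
CHD4	c.226A>T	M76L	WES2	6	69	0.09	unknown
CREBBP	c.146_148delGAG	G49del	WES2	5	226	0.02	unknown
CSNK1A1	c.505A>C	T169P	WES2	5	178	0.03	unknown
CUL3	c.464A>T	D155V	WES2	32	98	0.33	unknown
DICER1	c.1A>T	M1L	WES2	7	90	0.08	potential
DPYD	c.170A>G	N57S	WES2	6	283	0.02	unknown
DPYD	c.229A>G	M77V	WES2	8	410	0.02	unknown
EP300	c.670C>T	Q224*	WES2	137	143	0.96	potential
EPHA5	c.1803A>T	E601D	WES2	5	106	0.05	unknown
ERBB3	c.2641G>C	E881Q	WES2	46	142	0.32	unknown
ETV1	c.68A>C	N23T	WES2	6	146	0.04	unknown
EWSR1	c.898A>T	M300L	WES2	6	82	0.07	unknown
EWSR1	c.988A>C	M330L	WES2	6	142	0.04	unknown
EXT1	c.[876T>C;877G>T]	[V292V;V293L]	WES2	12	453	0.03	unknown
FAM135B	c.1898T>A	L633*	WES2	67	318	0.21	potential
FANCD2	c.719C>A	S240*	WES2	8	164	0.05	potential
FANCD2	c.859C>T	H287Y	WES2	8	249	0.03	unknown
FAT3	c.6854C>A	P2285H	WES2	61	303	0.20	unknown
FLT1	c.2515G>T	G839*	WES2	57	289	0.20	unknown
FOXP1	c.1625A>T	K542I	WES2	12	150	0.08	unknown
GLI2	c.4112C>T	P1371L	WES2	6	197	0.03	unknown
IGF2	c.20A>C	Q7P	WES2	105	217	0.48	unknown
IKZF1	c.346G>C	D116H	WES2	6	276	0.02	unknown
KAT6A	c.4769G>T	G1590V	WES2	20	349	0.06	unknown
KDM5A	c.396G>A	M132I	WES2	10	304	0.03	unknown
KDM6A	c.2700_2724del	H900Qfs*11	WES2	260	267	0.97	potential
KDM6A	c.2327T>C	I776T	WES2	12	156	0.08	unknown
KDM6A	c.1423T>C	S475P	WES2	8	113	0.07	unknown
KDM6A	c.2038G>A	A680T	WES2	9	163	0.06	unknown
NCOR1	c.5609C>A	T1870N	WES2	14	150	0.09	confirmed_somatic
NF1	c.4154A>G	K1385R	WES2	20	234	0.09	unknown
NFIB	c.1346G>C	S449T	WES2	13	292	0.05	unknown
NKX2-1	c.16A>G	S6G	WES2	5	219	0.02	unknown
NRG3	c.2090G>A	E355D	WES2	6	128	0.05	confirmed_somatic
NSD1	c.155_157dupCTG	T52ins	WES2	23	273	0.08	unknown
NSD1	c.158T>C	V53A	WES2	5	152	0.03	unknown
NTRK3	c.1698A>T	P541S	WES2	27	101	0.27	unknown
PLAG1	c.53T>C	V18A	WES2	10	245	0.04	confirmed_somatic
RANBP2	c.2591C>A	D1157H	WES2	101	276	0.37	unknown
RHOA	c.209G>T	E186K	WES2	15	144	0.10	unknown
SMARCA4	c.1930G>A	A1423A	WES2	7	277	0.03	unknown
SSX1	c.358G>A	K153N	WES2	136	257	0.53	unknown
TCF7L2	c.670G>A	S467A	WES2	13	172	0.08	unknown
TEK	c.2932G>A	S1084*	WES2	40	129	0.31	unknown
TERT	c.2105C>T	E507V	WES2	130	645	0.20	unknown
TP53	c.31G>A	E258K	WES2	121	128	0.95	potential
ZNF703	c.58A>G	G21ins	WES2	54	599	0.09	unknown
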