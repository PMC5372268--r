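ensembl_id	symbol	direction
ENSG00000125257	ABCC4	up
ENSG00000114770	ABCC5	down
ENSG00000173208	ABCD2	up
ENSG00000151726	ACSL1	down
ENSG00000135074	ADAM19	down
ENSG00000154027	AK5	up
ENSG00000151150	ANK3	up
ENSG00000206560	ANKRD28	up
ENSG00000118520	ARG1	down
ENSG00000196914	ARHGEF12	up
ENSG00000156802	ATAD2	up
ENSG00000085224	ATRX	up
ENSG00000023445	BIRC3	up
ENSG00000102010	BMX	down
ENSG00000136492	BRIP1	up
ENSG00000197603	C5orf42	up
ENSG00000152495	CAMK4	up
ENSG00000137812	CASC5	up
ENSG00000138778	CENPE	up
ENSG00000198707	CEP290	up
ENSG00000106034	CPED1	up
ENSG00000103196	CRISPLD2	down
ENSG00000146122	DAAM2	down
ENSG00000035664	DAPK2	down
ENSG00000137628	DDX60	up
ENSG00000174485	DENND4A	up
ENSG00000135905	DOCK10	up
ENSG00000147459	DOCK5	down
ENSG00000088387	DOCK9	up
ENSG00000178904	DPY19L3	down
ENSG00000134765	DSC1	up
ENSG00000135636	DYSF	down
ENSG00000198919	DZIP3	up
ENSG00000102189	EEA1	up
ENSG00000151491	EPS8	up
ENSG00000089048	ESF1	up
ENSG00000198734	F5	down
ENSG00000140525	FANCI	up
ENSG00000138829	FBN2	down
ENSG00000139132	FGD4	down
ENSG00000122025	FLT3	down
ENSG00000161791	FMNL3	up
ENSG00000073910	FRY	down
ENSG00000162654	GBP4	up
ENSG00000182885	GPR97	down
ENSG00000106070	GRB10	down
ENSG00000084110	HAL	down
ENSG00000120694	HSPH1	up
ENSG00000140443	IGF1R	down
ENSG00000197081	IGF2R	down
ENSG00000115604	IL18R1	down
ENSG00000115594	IL1R1	down
ENSG00000115590	IL1R2	down
ENSG00000109452	INPP4B	up
ENSG00000102445	KIAA0226L	down
ENSG00000137261	KIAA0319	down
ENSG00000110318	KIAA1377	up
ENSG00000054523	KIF1B	down
ENSG00000138182	KIF20B	up
ENSG00000139116	KIF21A	up
ENSG00000068796	KIF2A	up
ENSG00000184445	KNTC1	up
ENSG00000126777	KTN1	up
ENSG00000123384	LRP1	down
ENSG00000186205	MARC1	down
ENSG00000257335	MGAM	down
ENSG00000171843	MLLT3	up
ENSG00000196549	MME	down
ENSG00000100985	MMP9	down
ENSG00000051825	MPHOSPH9	up
ENSG00000138119	MYOF	up
ENSG00000049759	NEDD4L	up
ENSG00000184613	NELL2	up
ENSG00000173145	NOC3L	up
ENSG00000179299	NSUN7	down
ENSG00000111581	NUP107	up
ENSG00000159339	PADI4	down
ENSG00000123836	PFKFB2	down
ENSG00000075651	PLD1	down
ENSG00000101868	POLA1	up
ENSG00000080839	RBL1	up
ENSG00000257743	RP11-1220K2.2	down
ENSG00000226891	RP11-182I10.3	down
ENSG00000258476	RP11-76E17.3	down
ENSG00000140386	SCAPER	up
ENSG00000018280	SLC11A1	down
ENSG00000140090	SLC24A4	down
ENSG00000112053	SLC26A8	down
ENSG00000157800	SLC37A3	down
ENSG00000136824	SMC2	up
ENSG00000163029	SMC6	up
ENSG00000009694	TENM1	down
ENSG00000169902	TPST1	down
ENSG00000198677	TTC37	up
ENSG00000155657	TTN	up
ENSG00000120800	UTP20	up
ENSG00000197969	VPS13A	up
ENSG00000163625	WDFY3	down
ENSG00000213799	ZNF845	up
ENSG00000167232	ZNF91	up
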