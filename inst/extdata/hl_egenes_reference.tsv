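snp_id	snp_chr	snp_pos	major_allele	minor_allele	maf	egene_id	egene_chr	beta	p
rs2476601	1	114377568	G	A	0.10	OTUB2	14	0.09	4.07e-06
rs13034020	2	61043834	A	G	0.18	PUS10	2	0.28	1.01e-06
rs1432295	2	61066666	A	G	0.42	PRKACB	1	2.55	3.44e-06
rs1432295	2	61066666	A	G	0.42	RPL18A	19	-13.41	3.36e-05
rs3806624	3	27764623	A	G	0.46	OIP5	15	0.64	9.73e-06
rs3806624	3	27764623	A	G	0.46	CEP76	18	0.11	1.23e-05
rs3806624	3	27764623	A	G	0.46	H2AFZ	4	8.92	1.26e-05
rs3806624	3	27764623	A	G	0.46	CCNB2	15	1.72	3.73e-05
rs6439924	3	140169657	A	C	0.15	RP11-392P7.1	12	8.15	9.50e-06
rs6439924	3	140169657	A	C	0.15	OXA1L	14	7.41	1.17e-05
rs6439924	3	140169657	A	C	0.15	LA16c-306E5.1	16	0.04	1.48e-05
rs6439924	3	140169657	A	C	0.15	SETD6	16	1.18	1.57e-05
rs6439924	3	140169657	A	C	0.15	ZNF311	6	0.03	2.36e-05
rs6439924	3	140169657	A	C	0.15	RPL23AP65	11	26.59	2.86e-05
rs6439924	3	140169657	A	C	0.15	OVCH1-AS1	12	0.27	2.88e-05
rs6439924	3	140169657	A	C	0.15	RPL3P9	8	1.38	3.11e-05
rs20541	5	131995964	G	A	0.23	NR6A1	9	0.42	2.02e-06
rs20541	5	131995964	G	A	0.23	PDLIM4	5	0.72	2.35e-05
rs2069757	5	131998413	G	A	0.08	GPRC5C	17	2.11	1.47e-07
rs2069757	5	131998413	G	A	0.08	FBXO27	19	0.83	1.47e-07
rs2069757	5	131998413	G	A	0.08	APOC2	19	1.26	3.61e-07
rs2069757	5	131998413	G	A	0.08	SLC35G2	3	0.37	3.68e-07
rs2069757	5	131998413	G	A	0.08	CD2	1	0.82	4.03e-07
rs2069757	5	131998413	G	A	0.08	KCNRG	13	0.40	1.12e-06
rs2069757	5	131998413	G	A	0.08	APOC4-APOC2	19	0.10	1.31e-06
rs2069757	5	131998413	G	A	0.08	OTP	5	0.48	1.41e-06
rs2069757	5	131998413	G	A	0.08	CDC42EP5	19	0.73	3.84e-06
rs2069757	5	131998413	G	A	0.08	ZNF853	7	0.06	3.99e-06
rs2069757	5	131998413	G	A	0.08	TMEM132B	12	0.30	4.05e-06
rs2069757	5	131998413	G	A	0.08	DUSP15	20	0.84	6.44e-06
rs2069757	5	131998413	G	A	0.08	SYNPO2L	10	0.64	6.72e-06
rs2069757	5	131998413	G	A	0.08	PROSER2	10	0.29	8.48e-06
rs2069757	5	131998413	G	A	0.08	TNFRSF10C	8	0.74	1.44e-05
rs2069757	5	131998413	G	A	0.08	PRAM1	19	0.03	2.41e-05
rs2069757	5	131998413	G	A	0.08	WFIKKN1	16	0.05	3.12e-05
rs2069757	5	131998413	G	A	0.08	C12orf4	12	2.73	3.93e-05
rs27524	5	96101944	G	A	0.35	ERAP1	5	8.07	3.60e-38
rs27524	5	96101944	G	A	0.35	ERAP2	5	-4.84	1.52e-07
rs27524	5	96101944	G	A	0.35	EIF2AK2	2	1.77	1.08e-05
rs1002658	6	137981584	C	T	0.16	MTCYBP18	5	1.16	2.00e-05
rs2858870	6	32572251	T	C	0.12	HLA-DQB1-AS1	6	-4.01	7.29e-15
rs2858870	6	32572251	T	C	0.12	HLA-DQB1	6	-147.20	9.36e-14
rs2858870	6	32572251	T	C	0.12	HLA-DRB1	6	-118.50	5.63e-13
rs2858870	6	32572251	T	C	0.12	HLA-DQA1	6	-112.40	1.39e-10
rs2858870	6	32572251	T	C	0.12	HLA-DRB5	6	-54.28	5.95e-09
rs2858870	6	32572251	T	C	0.12	DPYSL3	5	0.17	1.52e-07
rs2858870	6	32572251	T	C	0.12	AC007163.6	2	0.02	1.66e-05
rs2858870	6	32572251	T	C	0.12	DSE	6	13.96	1.66e-05
rs2858870	6	32572251	T	C	0.12	CHORDC2P	14	0.01	3.28e-05
rs2858870	6	32572251	T	C	0.12	TAP2	6	3.38	3.76e-05
rs649775	6	33684313	G	A	0.07	RP11-131H24.4	14	0.06	3.57e-05
rs6928977	6	135626348	G	T	0.42	AHI1	6	-0.75	1.44e-15
rs7745098	6	135415004	T	C	0.47	ALDH8A1	6	0.08	9.36e-19
rs7745098	6	135415004	T	C	0.47	CTA-212D2.2	6	0.06	5.26e-16
rs7745098	6	135415004	T	C	0.47	PIGL	17	-0.44	9.53e-07
rs7745098	6	135415004	T	C	0.47	ADNP2	18	-0.39	1.04e-05
rs7745098	6	135415004	T	C	0.47	ALDH3A1	17	-0.03	1.94e-05
rs7745098	6	135415004	T	C	0.47	NDUFB2-AS1	7	0.04	3.29e-05
rs9482849	6	128288536	T	C	0.16	CEP162	6	0.43	3.08e-05
rs9482849	6	128288536	T	C	0.16	GNAI2	3	6.56	3.77e-05
rs2608053	8	129075832	C	T	0.46	LINC00621	13	0.23	3.61e-05
rs3781093	10	8101927	T	C	0.17	HSD11B1L	19	0.13	3.91e-05
rs7111520	11	111249611	A	G	0.31	COLCA2	11	-0.12	1.51e-06
rs7111520	11	111249611	A	G	0.31	COLCA1	11	-0.06	1.78e-06
rs7111520	11	111249611	A	G	0.31	CCDC13	3	0.20	3.16e-06
rs7111520	11	111249611	A	G	0.31	HEXIM2	17	0.19	3.32e-06
rs7111520	11	111249611	A	G	0.31	KHDC1	6	0.20	1.61e-05
rs112998813	13	115059729	T	C	0.08	UPF3AP2	17	-1.56	8.10e-10
rs112998813	13	115059729	T	C	0.08	CDC16	13	2.94	1.24e-08
rs112998813	13	115059729	T	C	0.08	MT3	16	1.06	6.78e-06
rs112998813	13	115059729	T	C	0.08	AL928768.3	14	112.90	6.95e-06
rs112998813	13	115059729	T	C	0.08	ZNF534	19	0.06	7.98e-06
rs112998813	13	115059729	T	C	0.08	TATDN1	8	0.72	8.03e-06
rs6565176	16	30174926	C	T	0.43	RP11-345J4.5	16	-2.52	2.43e-10
rs6565176	16	30174926	C	T	0.43	TBX6	16	0.07	3.09e-08
rs6565176	16	30174926	C	T	0.43	RP11-166B2.1	16	0.55	8.92e-07
rs6565176	16	30174926	C	T	0.43	AC006014.7	7	-0.16	1.29e-05
rs6565176	16	30174926	C	T	0.43	NPIPB11	16	0.61	2.15e-05
rs6565176	16	30174926	C	T	0.43	FAM13B	5	0.44	3.38e-05
rs1860661	19	1650134	A	G	0.40	RP11-93B14.6	20	0.01	1.29e-05
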