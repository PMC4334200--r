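gene	human_ortholog	direction	tier
Atg1	ULK1/ULK2	positive_regulator	multi
Atg18	WIPI1/WIPI2	positive_regulator	multi
Atg2	ATG2A/ATG2B	positive_regulator	multi
Atg6	BECN1	positive_regulator	multi
Atg9	ATG9A/B	positive_regulator	multi
Aut1	ATG3	positive_regulator	multi
CG10253	AGPS	positive_regulator	multi
CG12360	TRABD	positive_regulator	multi
CG1347	RB1CC1	positive_regulator	multi
CG31033	ATG16L1	positive_regulator	multi
CG31935	RAB3GAP1	positive_regulator	multi
CG32226	TECPR1	positive_regulator	multi
CG41099	ANKFY1	positive_regulator	multi
CG6199	PLOD3	positive_regulator	multi
CG7053	ATG101	positive_regulator	multi
CG7112	RABGAP1/1L	positive_regulator	multi
CG8678	WIPI1/WIPI2	positive_regulator	multi
Chc	CLTC	positive_regulator	multi
Cul-2	CUL2	positive_regulator	multi
garz	GBF1	positive_regulator	multi
Hel25E	DDX39B	positive_regulator	multi
Khc	KIF5B	positive_regulator	multi
Mcm2	MCM2	positive_regulator	multi
Pi3K59F	PIK3C3	positive_regulator	multi
Pros26.4	PSMC1	positive_regulator	multi
Rab3-GAP	RAB3GAP2	positive_regulator	multi
Rpn1	PSMD2	positive_regulator	multi
Rpt1	PSMC2	positive_regulator	multi
sgg	GSK3B	positive_regulator	multi
shi	DNM2	positive_regulator	multi
Tao-1	TAOK1	positive_regulator	multi
ade2	PFAS	negative_regulator	multi
Cctgamma	CCT3	negative_regulator	multi
Cdc37	CDC37	negative_regulator	multi
CG42233	WDR22	negative_regulator	multi
CG9485	AGL	negative_regulator	multi
Gp93	HSP90B1	negative_regulator	multi
Nek2	NEK7	negative_regulator	multi
Nipsnap	GBAS/NIPSNAP1	negative_regulator	multi
pk	PRICKLE2	negative_regulator	multi
Pk92B	MAP3K6/MAP3K15/MAP3K5	negative_regulator	multi
Pros45	PSMC5	negative_regulator	multi
Rpt3R	PSMC4	negative_regulator	multi
Atg12	ATG12	positive_regulator	single
Atg13	ATG13	positive_regulator	single
Atg5	ATG5	positive_regulator	single
Atg7	ATG7	positive_regulator	single
CG13745	FANCI	positive_regulator	single
CG6904	GYS1	positive_regulator	single
gish	CSNK1G3	positive_regulator	single
Mhc	MYH2	positive_regulator	single
Nup154	NUP155	positive_regulator	single
pic	DDB1	positive_regulator	single
Rab1	RAB1A	positive_regulator	single
Sas	NANS	positive_regulator	single
Sec61alpha	SEC61A2	positive_regulator	single
slim	KIAA0265	positive_regulator	single
Usp7	USP7	positive_regulator	single
Vps16A	PTPRA	positive_regulator	single
aPKC	PRKCI	negative_regulator	single
CG3590	ADSL	negative_regulator	single
CG9784	INPP5K	negative_regulator	single
Gfat1	GFPT1	negative_regulator	single
Mpk2	MAPK14	negative_regulator	single
Nat1	NARG1	negative_regulator	single
Nedd4	NEDD4	negative_regulator	single
Nsf2	NSF	negative_regulator	single
Pfk	PFKL/PFKP	negative_regulator	single
Rpt6R	PSMC5	negative_regulator	single
Stlk	LYK5	negative_regulator	single
Tcp-1eta	CCT7	negative_regulator	single
Tudor-SN	SND1	negative_regulator	single
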