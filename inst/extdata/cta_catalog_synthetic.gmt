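CTA	curated synthetic stand-in for a 276-gene cancer-testis antigen catalogue (CTA gene families); override via GMT	MAGEA1	MAGEA2B	MAGEA3	MAGEA4	MAGEA6	MAGEA8	MAGEA9	MAGEA9B	MAGEA10	MAGEA11	MAGEA12	MAGEB1	MAGEB2	MAGEB3	MAGEB4	MAGEB6	MAGEB10	MAGEB16	MAGEB18	MAGEC1	MAGEC2	MAGEC3	GAGE1	GAGE2A	GAGE2B	GAGE2C	GAGE2D	GAGE2E	GAGE4	GAGE5	GAGE6	GAGE7	GAGE8	GAGE10	GAGE12B	GAGE12C	GAGE12D	GAGE12E	GAGE12F	GAGE12G	GAGE12H	GAGE12I	GAGE12J	GAGE13	PAGE1	PAGE2	PAGE2B	PAGE3	PAGE4	PAGE5	XAGE1A	XAGE1B	XAGE1C	XAGE1D	XAGE1E	XAGE2	XAGE3	XAGE5	CTAG1A	CTAG1B	CTAG2	SSX1	SSX2	SSX2B	SSX3	SSX4	SSX4B	SSX5	SSX6	SSX7	SSX8	SSX9	SPANXA1	SPANXA2	SPANXB1	SPANXC	SPANXD	SPANXN1	SPANXN2	SPANXN3	SPANXN4	SPANXN5	CT45A1	CT45A2	CT45A3	CT45A5	CT45A6	CT45A7	CT45A8	CT45A9	CT45A10	CT47A1	CT47A2	CT47A3	CT47A4	CT47A5	CT47A6	CT47A7	CT47A8	CT47A9	CT47A10	CT47A11	CT47B1	CSAG1	CSAG2	CSAG3	PRAME	BAGE	BAGE2	BAGE3	BAGE4	BAGE5	SPAG1	SPAG4	SPAG6	SPAG8	SPAG9	SPAG11A	SPAG11B	SPAG17	AKAP3	AKAP4	SPA17	ACTL8	ADAM2	ADAM29	ARMC3	ATAD2	CTCFL	BRDT	CABYR	CAGE1	CALR3	CCDC33	CCDC36	CCDC62	CCDC83	CCDC110	CEP55	CPXCR1	CRISP2	DAZ1	DAZ2	DAZ3	DAZ4	DAZL	DDX43	DDX53	DKKL1	DMRT1	DPPA2	DPPA4	FATE1	FBXO39	FMR1NB	FTHL17	GPAT2	HORMAD1	HORMAD2	IGF2BP3	IL13RA2	KIF20B	LDHC	LEMD1	LUZP4	LY6K	MAEL	MORC1	NLRP4	NOL4	NXF2	NXF2B	ODF1	ODF2	ODF3	ODF4	OIP5	PASD1	PBK	PIWIL1	PIWIL2	PLAC1	POTEA	POTEB	POTEC	POTED	POTEE	POTEG	POTEH	PRM1	PRM2	PRSS54	PRSS55	RBM46	REC8	RGS22	RNF17	ROPN1	ROPN1B	SAGE1	SEMG1	SEMG2	SLCO6A1	SMC1B	SPATA19	SPEF2	SPO11	SYCE1	SYCP1	SYCP3	TAF7L	TDRD1	TDRD6	TEKT2	TEKT5	TEX14	TEX15	TEX101	TFDP3	THEG	TNP1	TNP2	TPTE	TPTE2	TSGA10	TSPY1	TSPY2	TSPY3	TSSK6	TULP2	ZNF165	ZNF645	TDRD5	TDRD9	TDRD12	SPATA22	SPACA3	MOV10L1	BOLL	RBMY1A1	USP26	MND1	PRDM7	PRDM9	HEMGN	GTSF1	PRSS50	CTAGE1	ACRBP	ACTL7A	ACTL7B	ADAD1	ASZ1	CATSPER1	CATSPER2	CATSPER3	CATSPER4	CCIN	CDY1	CDY2A	CLGN	CRISP1	DDX4	DNAJB8	ESX1	FSCN3	GMCL1	IZUMO1	IZUMO2	IZUMO3	IZUMO4	LDHAL6B	MS4A13	NXF3	PGK2	PIWIL3
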