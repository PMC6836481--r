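term	k_printed	K	p_corrected	genes
Brown fat cell differentiation	12	26	8.3154e-21	PPARG;PIK3R1;MRAP;PPARGC1A;SLC2A4;ADIG;ADIPOQ;ADRB1;PRDM16;ADRB3;CEBPB;FABP4;UCP1
Response to cold	10	29	7.84828e-16	PPARG;ACOT11;PMCH;AGT;ADRB1;UCP3;GMPR;ADRB3;TRH;IL6
Positive regulation of transcription from RNA polymerase II promoter	20	578	2.90244e-12	NFKB1;PPARG;NFE2L2;TWIST1;SREBF1;PPARA;PIK3R1;LPIN2;ESR1;CTNNB1;HNF4A;IL10;RXRA;EN1;TGFB1;ESRRA;IL6;CREBBP;PPARGC1B
Lipid biosynthetic process	8	29	7.45936e-12	SREBF1;DGAT2L6;MOGAT2;DGAT2;PRKAA2;MOGAT3;MOGAT1;AWAT1
Cellular lipid metabolic process	11	128	6.70379e-11	CYP7A1;LPIN1;PPARA;DGAT2;PRKAA2;LPIN2;AGT;DGAT1;RXRA;CREBBP;UCP1
Glucose homeostasis	9	64	7.26406e-11	PPARG;SLC2A4;PMCH;IRS1;PRKAA2;DBH;HNF4A;ADIPOQ;INS
Response to drug	14	301	1.68321e-10	PPARG;FXN;SREBF1;PIK3R1;CTNNB1;HNF4A;IL10;LPL;CYP19A1;TGFB1;NOS3;IL6;LIPE;CFTR
Lipid metabolic process	13	241	1.74841e-10	FADS2;PPARG;SREBF1;PPARA;LPIN2;LEP;LPL;UCP3;CIDEA;APOC3;LPIN3;FABP4;LIPE
Triglyceride biosynthetic process	7	33	7.84617e-10	LPN1;MOGAT2;DGAT2;LPIN2;LPL;DGAT1;GPAT2
Response to hypoxia	11	175	9.5641e-10	PPARA;LEP;NRF1;MMP2;UCP2;UCP3;TRH;TGFB1;ADIPOQ;NOS3;CREBBP
Positive regulation of MAPK cascade	8	61	1.16264e-09	LEP;CTNNB1;AGT;IGF1R;CNTF;ADRB3;IL6;INS
Response to insulin stimulus	8	62	1.2526e-09	MC4R;RETN;PPARA;IRS1;LEP;IL10;UCP3;IL6
Aging	9	114	5.88491e-09	SREBF1;AGT;ADRB1;UCP3;ADRB3;RXRA;TGFB1;NOS3;IL6
Response to estradiol stimulus	8	89	1.57804e-09	PIK3R1;ESR1;DBH;NRF1;CTNNB1;CYP19A1;TGFB1;NOS3
Cellular lipid metabolic process	7	56	1.62076e-08	PPARG;LPIN1;SLC2A4;IRS1;UCP2;RXRA;ADIPOQ
Response to organic cyclic compound	8	112	8.05856e-08	FXN;STC1;DBH;CYP19A1;RXRA;TRH;NOS3;IL6
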