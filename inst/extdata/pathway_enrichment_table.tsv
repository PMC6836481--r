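term	k_printed	K	p_corrected	genes
PPAR signaling pathway	10	70	1.27872e-14	CYP7A1;FADS2;FABP4;PPARA;ADIPOQ;UCP1;LPL;RXRA;PPARG;APOC3
Adipocytokine signaling pathway	9	67	3.87352e-13	IRS1;SLC2A4;PPARA;ADIPOQ;NFKB1;LEP;PRKAA2;RXRA;PPARGC1A
Pathways in cancer	11	324	1.10046e-09	IL6;MMP2;IGF1R;FGF19;NFKB1;PIK3R1;TGFB1;CTNNB1;CREBBP;RXRA;PPARG
Insulin signaling pathway	8	133	4.39226e-09	IRS1;LIPE;SLC2A4;SREBF1;PIK3R1;PRKAA2;INS;PPARGC1A
Prostate cancer	6	88	1.89023e-07	IGF1R;NFKB1;PIK3R1;INS;CTNNB1;CREBBP
Type II diabetes mellitus	5	46	2.15133e-07	IRS1;SLC2A4;ADIPOQ;PIK3R1;INS
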