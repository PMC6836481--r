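PPARG
CREBBP
LEP
INS
ADIPOQ
LPL
FABP4
IL6
PIK3R1
MRAP
PPARGC1A
SLC2A4
ADIG
ADRB1
PRDM16
ADRB3
CEBPB
UCP1
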