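ligand	receptor
TGFB1	TGFBR1
TGFB2	TGFBR2
HGF	MET
SPP1	CD44
PDGFA	PDGFRA2
PDGFB	PDGFRB2
FN1	ITGA5
VEGFA	FLT1
VEGFB	FLT4
IGF1	IGF1R
IGF2	IGF2R
EGF	EGFR2
TGFA	ERBB3
NRG1	ERBB4
FGF2	FGFR1
FGF7	FGFR2
WNT5A	FZD1
JAG1	NOTCH1
DLL1	NOTCH2
CXCL12	CXCR4
CCL2	CCR2
IL6	IL6R
LIF	LIFR
OSM	OSMR
BMP2	BMPR1A
BMP4	BMPR2
GDF15	TGFBR3
ANGPT1	TEK
ANGPT2	TIE1
EFNB2	EPHB4
SEMA3A	NRP1
SLIT2	ROBO1
NTN1	DCC
GAS6	AXL
PROS1	MERTK
MDK	PTPRZ1
PTN	ALK
HBEGF	CD9
AREG	ICAM1
BTC	ERBB2
LGND41	RCPT41
LGND42	RCPT42
LGND43	RCPT43
LGND44	RCPT44
LGND45	RCPT45
LGND46	RCPT46
LGND47	RCPT47
LGND48	RCPT48
LGND49	RCPT49
LGND50	RCPT50
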