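symbol_a	symbol_b
IQSEC1	ARF6
ARF6	PSD3
PSD3	DNM2
DNM2	BTBD7
BTBD7	CTNNB1
CTNNB1	GLIS3
LRBA	VAMP7
VAMP7	IQSEC1
ARF6	GIT1
GIT1	PXN
CTNNB1	CDH1
EGFR	GRB2
GRB2	SOS1
SOS1	HRAS
ACTB	TUBB
TUBB	MAP1B
CLTC	AP2A1
AP2A1	EPS15
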