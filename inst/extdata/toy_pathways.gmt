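R-TOY-01	Toll-like receptor cascades	TLR4	MYD88	IRAK1	IRAK4	JUN	FOS	NFKB1	TRAF6
R-TOY-02	MyD88 cascade initiated on plasma membrane	MYD88	IRAK1	IRAK4	TRAF6
R-TOY-03	Signaling by interleukins	IL6	IL1B	IL13	STAT3	JAK1	JUN
R-TOY-04	MAP kinase activation	MAPK1	MAPK3	JUN	FOS	EGR1	FOSB
R-TOY-05	Oxidative stress induced senescence	NFE2L2	HMOX1	EGR1	FOSB	NR4A1	KLF4
R-TOY-06	G1 phase of the mitotic cell cycle	CCND1	CDK4	CDK6	RB1	E2F1
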