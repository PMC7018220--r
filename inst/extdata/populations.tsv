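# Population panel: proportion surviving glyphosate at 1.7 kg a.i./ha;
# usage flags: E = candidate-gene (EPSPS) sequencing, P = population genomics
population	survival	usage	state
SH4	0.1	E,P	VA
CR	0.21	E	NC
IN12	0.25	E	IN
MA1	0.25	E	SC
SN	0.5	E	TN
RB	0.18	P	TN
HA	0.15	P	NC
FL	0.20	P	SC
MC	0.67	E	NC
CL1	0.73	E	SC
VA2	0.82	E	VA
WG	0.83	E,P	TN
BI	1	E,P	TN
DW	1	E,P	NC
SPC	0.71	P	TN
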