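patient	A	B	C	D	E	F
P1	1	0	0	1	0	0
P2	1	1	0	0	0	0
P3	0	0	1	0	0	1
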