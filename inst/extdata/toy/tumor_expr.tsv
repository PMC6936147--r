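patient	A	B	C	D	E	F
P1	1	9	1	1	9	2
P2	9	1	2	1	1	2
P3	1	1	3	9	1	2
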