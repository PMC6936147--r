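sample	A	B	C	D	E	F
S1	1	2	1	2	6	3
S2	2	3	3	1	5	1
S3	3	3	2	4	4	4
S4	4	5	5	3	3	1
S5	5	5	4	6	2	5
S6	6	7	6	5	1	9
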