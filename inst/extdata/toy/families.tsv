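# family	species	protein
F1	A	a1
F1	B	b1
F2	A	a2
F2	B	b2
F2	C	c2
F2	D	d2
F3	A	a3
F4	A	a4
F4	C	c4
F5	A	a5
F5	B	b5
F5	D	d5
F6	B	b6
F6	C	c6
F7	A	a7
F7	B	b7
F8	A	a8
F8	B	b8
F8	C	c8
F8	D	d8
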