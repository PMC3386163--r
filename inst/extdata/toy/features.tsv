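protein	length
a1	210
a2	640
a3	95
a4	180
a5	450
a7	260
a8	520
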