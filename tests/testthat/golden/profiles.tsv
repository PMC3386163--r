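#phylostrat	1.0.0
#config	ages=node_ages.tsv
#config	families=families.tsv
#config	out=profiles.tsv
#config	restrict_to_tree=FALSE
#config	species=A
#config	tree=tree.nwk
protein	A	B	C	D
a1	1	1	0	0
a2	1	1	1	1
a3	1	0	0	0
a4	1	0	1	0
a5	1	1	0	1
a7	1	1	0	0
a8	1	1	1	1
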