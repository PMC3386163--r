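#phylostrat	1.0.0
#config	ages=node_ages.tsv
#config	algorithm=wagner
#config	families=families.tsv
#config	gain_penalty=1
#config	loss_penalty=1
#config	out=ages.tsv
#config	restrict_to_tree=FALSE
#config	species=A
#config	tree=tree.nwk
#species	A
#db_name	families.tsv
#method	wagner
#gain_penalty	1
#loss_penalty	1
#stratum	Root	500
#stratum	AB	100
#stratum	A	0
protein	species	family	origin	age_mya	method	flag
a1	A	F1	AB	100	wagner	
a2	A	F2	Root	500	wagner	
a3	A	F3	A	0	wagner	
a4	A	F4	A	0	wagner	
a5	A	F5	AB	100	wagner	
a7	A	F7	AB	100	wagner	
a8	A	F8	Root	500	wagner	
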