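#phylostrat	1.0.0
#config	ages=ages.tsv
#config	bh=TRUE
#config	gaf=FALSE
#config	out=enrich.tsv
#config	set1=set1.txt
#species	A
#ages_method	wagner
#n1	3
#n2	4
#mean1_mya	33.333333333333336
#mean2_mya	300
#U	1
#p_overall	0.092230801270891574
#disjointified	true
stratum	age_mya	n1	n2	odds_ratio	p	q	stars
Root	500	0	2	0	0.42857142857142827	0.64285714285714235	
AB	100	1	2	0.5	1	1	
A	0	2	0	Inf	0.14285714285714285	0.42857142857142855	
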