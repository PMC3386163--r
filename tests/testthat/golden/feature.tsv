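#phylostrat	1.0.0
#config	ages=ages.tsv
#config	exclude_oldest=1
#config	features=features.tsv
#config	out=feature.tsv
#species	A
#ages_method	wagner
#rho	0.94491118252306794
#p	0.0095238095238095247
#n	7
#dropped_no_feature	0
#dropped_no_age	0
#trend_slope_per_mya	1.6916666666666673
#trend_intercept	137.49999999999997
#trend_n	5
stratum	n	q1	median	mean	q3	whisker_low	whisker_high
Root	2	520	580	580	640	520	640
AB	3	235	260	306.66666666666669	355	210	450
A	2	95	137.5	137.5	180	95	180
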