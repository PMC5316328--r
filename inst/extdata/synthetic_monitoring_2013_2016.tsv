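year	spring_count	autumn_count	prop_young	harvest_no	harvest_dk	days
2013	83095.0956388637	98525.2547241735	0.145159618891297	3390	7910	3
2014	81047.9594914536	102797.79607726	0.145159618891297	4440	10360	17
2015	70649.835894239	74479.1642608129	0.145159618891297	2010	4690	11
2016	93384.4243376257	90902.7069249878	0.145159618891297	1200	2800	15
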