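year	policy_indicator	support_ratio
2010	0	7.40
2011	0	7.07
2012	0	6.74
2013	0	6.41
2014	1	6.09
2015	1	5.76
2016	1	5.43
2017	1	5.10
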