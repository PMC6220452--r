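source	df	ss
Year	4	3.20
Variety	358	295.00
Season (Year)	5	202.00
Year x Variety	1432	55.66
Season (Year) x Variety	1790	68.74
Residual	7180	1.02
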