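source	df	ss
Variety	3	7.274
Temperature	1	0.239
Photoperiod	1	0.340
Variety x Temp	3	0.344
Variety x Photo	3	0.215
Temp x Photo	1	0.046
Variety x Temp x Photo	3	0.031
Residual	32	0.113
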