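class,T-N,TT-N,PC-N,S-N,T-MN,TT-MN,PC-MN,S-MN
T-N,0.75,0.12,0.01,0.00,0.10,0.00,0.00,0.00
TT-N,0.09,0.79,0.08,0.00,0.00,0.03,0.00,0.00
PC-N,0.01,0.10,0.76,0.10,0.00,0.00,0.03,0.00
S-N,0.00,0.00,0.12,0.85,0.00,0.00,0.01,0.01
T-MN,0.04,0.00,0.00,0.00,0.88,0.05,0.01,0.00
TT-MN,0.00,0.01,0.00,0.00,0.06,0.83,0.09,0.00
PC-MN,0.00,0.00,0.01,0.00,0.00,0.06,0.86,0.07
S-MN,0.00,0.00,0.00,0.00,0.00,0.00,0.05,0.94
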