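class,accuracy,iou,f1
T-N,0.75,0.70,0.56
TT-N,0.79,0.47,0.63
PC-N,0.76,0.61,0.76
S-N,0.85,0.75,0.66
T-MN,0.88,0.81,0.64
TT-MN,0.83,0.34,0.39
PC-MN,0.86,0.59,0.54
S-MN,0.94,0.92,0.69
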