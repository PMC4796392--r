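system,A,B,C
1,0.60,0.81,0.74
2,0.65,0.75,0.70
3,0.70,0.72,0.85
4,0.45,0.69,0.70
5,0.50,0.80,0.75
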