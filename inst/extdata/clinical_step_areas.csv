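step,S_mm2
0,117733.11
1,118504.79
2,119319.77
3,120392.57
4,122278.13
5,123252.50
6,123638.54
7,124240.53
8,124522.65
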