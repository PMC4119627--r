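step,V_mm3
0,3107136.50
1,3166015.68
2,3220374.85
3,3289162.78
4,3404764.16
5,3467026.40
6,3491925.98
7,3530934.93
8,3549148.62
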