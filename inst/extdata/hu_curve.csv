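hu,spr
-1000,0.001
-100,0.93
0,1.00
100,1.10
1600,1.85
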