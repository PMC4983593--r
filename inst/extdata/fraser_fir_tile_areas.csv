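tile,class96_km2,class97_km2,class98_km2
1,0,0,0
2,0,0,0
3,0,0,0
4,0,0,0
5,0,0,0
6,1,0,4
7,550,93,0
8,1924,185,5
9,0,0,0
10,374,0,0
11,201,0,0
12,0,0,0
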