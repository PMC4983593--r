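land_class,maxent_km2,lc_km2,soil_km2,lc_soil_km2
0,0,0,0,0
11,6082,6084,6082,6084
21,28238,28399,28250,28399
22,11394,11409,11395,11409
23,4124,4130,4125,4130
24,1512,1513,1512,1513
31,1924,1931,1925,1931
41,214155,214155,214362,214362
42,30205,30205,30243,30243
43,11719,11719,11741,11741
52,8645,8723,8659,8723
71,17597,17617,17598,17617
81,68813,68990,68846,68990
82,30339,30339,30339,30339
90,10306,10308,10306,10308
95,682,682,682,682
96,3693,3255,3428,3050
97,305,278,305,278
98,75,71,10,9
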