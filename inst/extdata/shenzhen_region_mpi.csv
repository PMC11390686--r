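region,effch,techch,pech,sech,tfpch
Luohu Hospital Group,1.068,0.969,1.061,1.007,1.020
Nanshan,1.092,0.946,1.040,1.075,1.013
Futian,1.016,0.985,0.997,1.024,0.999
Baoan,1.059,0.964,1.009,1.050,1.015
Longhua,0.947,0.999,0.937,1.009,0.926
Yantian,1.027,0.977,1.010,1.019,1.006
Pingshan,0.922,0.989,0.925,1.013,0.892
Guangming,1.038,0.961,1.020,1.016,1.009
Dapeng,1.070,0.977,1.016,1.060,1.039
Luohu,1.022,0.973,0.992,1.030,0.985
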