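chc,effch,techch,pech,sech,tfpch
C1,0.971,1.050,1.020,0.937,0.947
C2,1.000,0.979,1.000,1.000,0.979
C3,0.953,1.062,0.956,0.997,0.998
C4,1.140,1.052,1.064,1.013,1.097
C5,1.000,1.412,1.000,1.000,1.412
C6,0.968,0.988,0.961,1.029,0.955
C7,1.024,1.079,1.013,1.006,1.010
C8,0.965,1.011,1.000,0.965,0.969
C9,1.044,1.125,1.023,1.003,1.095
C10,1.000,1.055,1.000,1.000,1.055
C11,1.000,1.122,1.000,1.000,1.122
C12,1.000,1.089,1.000,1.000,1.089
C13,1.042,1.144,1.022,1.000,1.057
C14,0.976,1.067,1.007,0.979,1.062
C15,1.022,1.057,1.036,0.983,1.022
C16,1.137,1.048,1.134,1.004,1.155
C17,1.024,1.062,1.000,1.024,1.089
C18,1.064,1.112,1.000,1.064,1.170
C19,1.009,1.110,1.000,1.009,1.099
C20,1.053,1.213,1.000,1.053,1.185
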