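class,year,GR,CR,WS,SFR,WD,BD,FP,RM,EC
CL,2000,2.467,4.392,2.961,7.204,8.092,3.503,4.934,0.493,0.049
CL,2005,2.431,4.327,2.917,7.098,7.973,3.452,4.861,0.486,0.049
CL,2010,2.418,4.304,2.902,7.060,7.931,3.434,4.836,0.484,0.048
CL,2018,2.322,4.133,2.786,6.779,7.615,3.297,4.643,0.464,0.046
WO,2000,13.930,10.746,12.736,15.522,5.214,12.975,0.398,10.348,5.095
WO,2005,13.916,10.735,12.723,15.506,5.208,12.962,0.398,10.337,5.089
WO,2010,13.907,10.728,12.715,15.496,5.205,12.953,0.397,10.331,5.086
WO,2018,13.940,10.754,12.745,15.534,5.218,12.984,0.398,10.356,5.098
GL,2000,0.131,0.148,0.131,0.320,0.215,0.179,0.049,0.008,0.007
GL,2005,0.130,0.146,0.130,0.317,0.213,0.177,0.049,0.008,0.006
GL,2010,0.125,0.140,0.125,0.304,0.204,0.170,0.047,0.008,0.006
GL,2018,0.122,0.137,0.122,0.297,0.200,0.166,0.046,0.008,0.006
WA,2000,0.000,0.604,26.743,0.013,23.856,3.267,0.131,0.013,5.695
WA,2005,0.000,0.634,28.081,0.014,25.050,3.431,0.138,0.014,5.980
WA,2010,0.000,0.635,28.121,0.014,25.086,3.436,0.138,0.014,5.989
WA,2018,0.000,0.632,27.990,0.014,24.968,3.420,0.137,0.014,5.961
WL,2000,0.288,2.733,2.477,0.273,2.906,0.400,0.048,0.011,0.887
WL,2005,0.279,2.647,2.400,0.265,2.814,0.387,0.046,0.011,0.859
WL,2010,0.299,2.837,2.572,0.284,3.017,0.415,0.050,0.012,0.921
WL,2018,0.369,3.506,3.178,0.351,3.728,0.513,0.062,0.014,1.138
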