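class,FP,RM,GR,CR,WS,WD,SFR,BD,EC
CL,1793.88,179.39,896.94,1596.55,1076.33,2941.96,2619.06,1273.65,17.94
WO,179.39,4664.08,6278.58,4843.47,5740.41,2349.98,6996.13,5848.04,2296.16
GL,538.16,89.69,1435.10,1614.49,1435.10,2349.98,3498.06,1955.33,71.76
WA,179.39,17.94,0.00,825.18,36559.25,32612.71,17.94,4466.76,7785.43
CO,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00
UL,17.94,0.00,0.00,0.00,53.82,17.94,35.88,609.92,17.94
WL,538.16,125.57,3228.98,30675.33,27805.12,32612.71,3067.53,4484.70,9956.03
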