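raw_code,class_code,class,raw_label
11,1,CL,paddy field
12,1,CL,dry land
21,2,WO,forest
22,2,WO,shrubland
23,2,WO,open woodland
24,2,WO,other woodland
31,3,GL,high-cover grassland
32,3,GL,medium-cover grassland
33,3,GL,low-cover grassland
41,4,WA,river and canal
42,4,WA,lake
43,4,WA,reservoir and pond
44,4,WA,permanent ice and snow
45,7,WL,tidal flat
46,7,WL,bottomland shoal
51,5,CO,urban built-up
52,5,CO,rural settlement
53,5,CO,other construction
61,6,UL,sandy land
62,6,UL,gobi
63,6,UL,saline-alkali land
64,7,WL,swamp and marsh
65,6,UL,bare soil
66,6,UL,bare rock
67,6,UL,other unused
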