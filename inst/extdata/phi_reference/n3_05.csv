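0.57067034997444466,0.46524650201529077,0.72171030619164289
0,1,0.815263141034268
1,0,1
0.35535560733457339,0.20928058657526105,1
0.64464439266542661,0.79071941342473895,0
0,1,0
1,0,0.184736858965732
0.42932965002555534,0.53475349798470928,0.27828969380835711
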