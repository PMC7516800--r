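0.016133179616201435,0.027564009216103594,0.011511979510467915
0,0.713559247732371,1
0.41764532221032352,0,0.58529873102698038
0,0,1
1,1,0
0.58235467778967642,1,0.41470126897301962
1,0.286440752267629,0
0.98386682038379858,0.97243599078389642,0.9884880204895321
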