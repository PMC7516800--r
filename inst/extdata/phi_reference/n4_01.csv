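0.00038229575976849166,0.001600664416811254,0.049115657675898004,7.0568766336750628e-05
0,0.90326251328827456,0.19977974305349064,0.2103625276472183
0.21573130829999368,0,0.050242075408862323,0.047714528951132533
0,0,0.20436148858864076,1
0.0015550020557795953,0.0016373740297725391,0,0.0070306180376647999
0,0.92397792178801896,0,1
0.87749502664026213,0,0,1
0,0,0,1
1,1,1,0
0.12250497335973787,1,1,0
1,0.076022078211981037,1,0
0.99844499794422037,0.99836262597022751,1,0.9929693819623352
1,1,0.79563851141135922,0
0.78426869170000635,1,0.94975792459113773,0.95228547104886752
1,0.09673748671172544,0.80022025694650933,0.7896374723527817
0.99961770424023155,0.99839933558318872,0.95088434232410202,0.99992943123366329
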