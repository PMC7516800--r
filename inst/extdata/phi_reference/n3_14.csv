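0.34138240039709417,0.48768923297378325,0.28842365009549342
0,0.84486971138524014,1
0.59140868937534707,0,0.69999987146619225
0,0,1
1,1,0
0.40859131062465293,1,0.30000012853380775
1,0.15513028861475986,0
0.65861759960290578,0.51231076702621681,0.71157634990450658
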