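0.073040538102687694,0.24444538382572947,0.25695934869582637
0,1,1
1,0,0.29880105305960664
0.048700173523985257,0.71575061007354579,1
0.95129982647601474,0.28424938992645421,0
0,1,0.70119894694039342
1,0,0
0.92695946189731226,0.75555461617427055,0.74304065130417363
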