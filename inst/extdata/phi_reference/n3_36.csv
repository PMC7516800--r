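3.5473268944275708e-05,0.006042132642633564,0.00027586458586912254
0,1,1
0.045656823870864657,0,0.0058709848065854591
0,0.87141057329807037,1
1,0.12858942670192958,0
0.95434317612913533,1,0.99412901519341457
1,0,0
0.99996452673105574,0.99395786735736646,0.99972413541413085
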