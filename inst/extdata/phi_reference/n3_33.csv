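0.13981750287462899,0.075020098734024987,0.15095857626250725
0,1,0.53655727782017193
1,0,1
0.50304182384729268,0.073802189075396929,1
0.49695817615270732,0.92619781092460307,0
0,1,0
1,0,0.46344272217982807
0.86018249712537098,0.92497990126597496,0.84904142373749281
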