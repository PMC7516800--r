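0.16210512712172392,0.16397313336793301,0.07028413854958114
0,0.4335713484053168,1
0.42863203932240074,0,0.98860785173862864
0,0,1
1,1,0
0.57136796067759921,1,0.01139214826137136
1,0.56642865159468325,0
0.83789487287827602,0.83602686663206693,0.92971586145041885
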