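0.068694500186067875,0.021498697639555583,0.21918282960686952
0,1,0.31296097331407302
1,0,1
0.90191431656340937,0.68658813142763209,1
0.098085683436590604,0.31341186857236791,0
0,1,0
1,0,0.68703902668592698
0.93130549981393207,0.97850130236044441,0.78081717039313048
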