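0.34458245187004322,0.53231285404869744,0.31189084392713518
0,0.90512689266243451,1
0.58591642406328692,0,0.64733069894742745
0,0,1
1,1,0
0.41408357593671308,1,0.35266930105257255
1,0.094873107337565488,0
0.65541754812995678,0.46768714595130256,0.68810915607286482
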