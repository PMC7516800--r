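0.24106087893331371,0.29878445393582231,0.35674336433720055
0,1,1
1,0,0.80680529310635607
0.1624666810805605,0.32427368514286237,1
0.8375333189194395,0.67572631485713763,0
0,1,0.19319470689364393
1,0,0
0.75893912106668626,0.70121554606417769,0.64325663566279945
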