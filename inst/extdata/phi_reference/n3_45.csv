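0.46692366188464546,0.53465475021138842,0.67859990495196265
0,1,1
1,0,0.87331808367930175
0.21212080003277334,0.31193084691384021,1
0.78787919996722666,0.68806915308615979,0
0,1,0.12668191632069825
1,0,0
0.53307633811535449,0.46534524978861158,0.32140009504803735
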