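0.61686660405067306,0.41612194365780997,0.54535105642518267
0,0.88406642999332197,0.67457362892614503
1,0,1
0.23696499941611782,0,1
0.76303500058388218,1,0
0,1,0
1,0.11593357000667803,0.32542637107385497
0.38313339594932694,0.58387805634219003,0.45464894357481733
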