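0.47038152617688223,0.45536540296990752,0.38001062851662687
0,0.80787745132177591,0.96807671566308906
0.83451800694164624,0,1
0,0,1
1,1,0
0.16548199305835376,1,0
1,0.19212254867822409,0.03192328433691094
0.52961847382311777,0.54463459703009254,0.61998937148337308
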