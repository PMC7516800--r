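0.030274762158508241,0.074749418619803443,0.01663622056667894
0,0.5495078864559666,1
0.22255986566658709,0,0.40501669066476875
0,0,1
1,1,0
0.77744013433341297,1,0.59498330933523125
1,0.4504921135440334,0
0.96972523784149178,0.92525058138019656,0.98336377943332109
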