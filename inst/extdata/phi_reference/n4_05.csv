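0.28808302684029713,0.41883736939187677,0.25883212830079666,0.39977780607242086
0,1,0.78626258118181214,0.63428049504634176
0.72022837611710067,0,0.43626824689501098,0.5408039512018632
0,0.045002971721853746,1,0.85803011743277258
0.87511896519619237,0.70596121925930866,0,1
0,1,0,1
1,0,0,1
0.54293249374225905,0.43341300883249001,0.24543445425876553,1
0.45706750625774101,0.56658699116750999,0.75456554574123447,0
0,1,1,0
1,0,1,0
0.12488103480380763,0.29403878074069134,1,0
1,0.95499702827814625,0,0.14196988256722742
0.27977162388289933,1,0.56373175310498902,0.4591960487981368
1,0,0.21373741881818786,0.36571950495365824
0.71191697315970282,0.58116263060812323,0.7411678716992034,0.60022219392757914
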