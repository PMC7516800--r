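0.11825091011562376,0.16898205112418516,0.064072084303256366,0.068171128636854428
0,0.34085030975083108,0.42467207312697514,0.36465614327279722
0.23852154162578604,0,0.25518047943193645,0.29717865781525138
0,0,1,1
0.78377127408981917,0.67300636915709044,0,0.62907051923671486
0,1,0,1
1,0,0,1
0.36746065844141385,0.26335590810792364,0.40875470089491739,1
0.63253934155858615,0.73664409189207636,0.59124529910508261,0
0,1,1,0
1,0,1,0
0.21622872591018083,0.32699363084290956,1,0.37092948076328514
1,1,0,0
0.76147845837421402,1,0.74481952056806355,0.70282134218474868
1,0.65914969024916892,0.57532792687302492,0.63534385672720273
0.88174908988437628,0.83101794887581482,0.93592791569674361,0.93182887136314552
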