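0.51577589918193512,0.21468270847255455,0.33215902044624579,0.21166851868750705
0,0.59970892087730443,0.37494482355119219,0.25233031294307839
1,0,0.6062243902876483,0.9008061472983101
0.30594240383591453,0,0.68431288346003538,1
0.58221361337987365,0.39181803304401652,0,0.93122687891288802
0,1,0,1
1,0,0,1
0.38514288824776155,0.086366245156029975,0,1
0.61485711175223845,0.91363375484397003,1,0
0,1,1,0
1,0,1,0
0.41778638662012635,0.60818196695598348,1,0.068773121087111977
0.69405759616408547,1,0.31568711653996462,0
0,1,0.3937756097123517,0.0991938527016899
1,0.40029107912269557,0.62505517644880781,0.74766968705692161
0.48422410081806488,0.78531729152744545,0.66784097955375421,0.78833148131249298
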