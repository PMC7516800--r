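0.32737537506830522,0.39577119583730613,0.21063093756344153,0.23539547881121342
0,0.46006976533432309,0.58094871709515861,0.68503214761391384
0.38056208629651339,0,0.5666472411780612,0.48055115216788297
0,0,1,1
0.90294572276303908,1,0,0.71506832626876637
0,1,0,1
1,0.060784612663152604,0,1
0.047294122251134163,0.1920477610064516,0.36015970763523286,1
0.95270587774886584,0.8079522389935484,0.63984029236476714,0
0,0.9392153873368474,1,0
1,0,1,0
0.097054277236960917,0,1,0.28493167373123363
1,1,0,0
0.61943791370348666,1,0.4333527588219388,0.51944884783211709
1,0.53993023466567691,0.41905128290484139,0.31496785238608616
0.67262462493169473,0.60422880416269387,0.78936906243655847,0.76460452118878663
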