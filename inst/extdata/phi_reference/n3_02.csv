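0.050756175905458424,0.18068439250970361,0.023986083241574786
0,0.47257467320337021,1
0.1327512736900428,0,0.28091068188267876
0,0,1
1,1,0
0.8672487263099572,1,0.71908931811732124
1,0.52742532679662979,0
0.94924382409454156,0.81931560749029642,0.97601391675842519
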