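0.21328719508449751,0.10915576906317324,0.13576864093664986
0,0.6365531736814426,0.51177835134420158
1,0,1
0.19601633845546351,0,1
0.80398366154453649,1,0
0,1,0
1,0.3634468263185574,0.48822164865579842
0.78671280491550255,0.89084423093682674,0.86423135906335014
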