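0.45399518925890764,0.2514096314391932,0.12547312689524967
0,0.27637545477094039,0.5537715759710784
0.49907844093712478,0,1
0,0,1
1,1,0
0.50092155906287528,1,0
1,0.72362454522905961,0.4462284240289216
0.54600481074109242,0.74859036856080685,0.8745268731047503
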