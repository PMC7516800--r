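0.0012077896246301368,1.638918169941787e-06,0.0012221982475323556
0,1,0.0013569566557948152
1,0,1
0.99865904064806932,0.011789104534646322,1
0.0013409593519306652,0.98821089546535368,0
0,1,0
1,0,0.99864304334420517
0.99879221037536992,0.99999836108183005,0.99877780175246766
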