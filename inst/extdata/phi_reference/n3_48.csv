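0.24394287429664616,0.13884038645359997,0.48744157556805262
0,1,0.5691512279418478
1,0,1
0.71516507123587325,0.49954438331945517,1
0.28483492876412675,0.50045561668054483,0
0,1,0
1,0,0.4308487720581522
0.75605712570335382,0.86115961354640003,0.51255842443194743
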