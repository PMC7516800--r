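0.40526948094717524,0.4454606014878138,0.49073573171828838
0,1,1
1,0,0.90977626212867657
0.092259697642040117,0.17415942073722046,1
0.90774030235795988,0.82584057926277954,0
0,1,0.090223737871323428
1,0,0
0.5947305190528247,0.55453939851218625,0.50926426828171167
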