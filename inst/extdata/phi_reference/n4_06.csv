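0.00094584074072574104,7.0126565612462654e-05,0.0024225642225871482,0.00054899916462160952
0,0.0028050677690003205,0.069415179916975364,0.53542137848830407
0.037833699016135175,0,1,0.93624583803394579
0,0,1,1
0.027101739792130812,0.20904434586627643,0,0.0010951814410863256
0,1,0,1
1,0,0.8615258060963773,1
0.077551687025205873,0.88040836959099034,0.99516730161466493,1
0.92244831297479413,0.11959163040900969,0.0048326983853350935,0
0,1,0.1384741939036227,0
1,0,1,0
0.97289826020786918,0.7909556541337236,1,0.99890481855891367
1,1,0,0
0.9621663009838648,1,0,0.063754161966054212
1,0.99719493223099964,0.93058482008302468,0.46457862151169593
0.99905415925927421,0.99992987343438755,0.99757743577741287,0.99945100083537841
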