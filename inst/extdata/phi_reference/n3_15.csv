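0.46035421284086864,0.53949932276566059,0.67511461164861408
0,1,1
1,0,0.85329896334426025
0.20087743109541667,0.31810954036871686,1
0.79912256890458333,0.68189045963128314,0
0,1,0.14670103665573975
1,0,0
0.53964578715913136,0.46050067723433941,0.32488538835138592
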