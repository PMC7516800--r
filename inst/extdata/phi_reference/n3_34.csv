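0.20949336360089671,0.45677283767221383,0.44020891094310155
0,1,1
0.96373705841721091,0,0.4586379625121928
0,0.52410467304698782,1
1,0.47589532695301212,0
0.036262941582789088,1,0.5413620374878072
1,0,0
0.79050663639910335,0.54322716232778623,0.55979108905689845
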