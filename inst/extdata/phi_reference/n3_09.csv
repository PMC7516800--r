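0.294162592001873,0.30715554458990735,0.44752466284092063
0,1,1
1,0,0.95769911103059646
0.31365672086078888,0.34268965170655297,1
0.68634327913921112,0.65731034829344703,0
0,1,0.042300888969403538
1,0,0
0.705837407998127,0.69284445541009265,0.55247533715907937
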