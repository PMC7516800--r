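0.38149261072863749,0.7083510693827566,0.37487912060214773
0,0.98266417240989734,1
0.52922786003388145,0,0.53856431820038453
0,0,1
1,1,0
0.47077213996611855,1,0.46143568179961547
1,0.017335827590102659,0
0.61850738927136251,0.2916489306172434,0.62512087939785221
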