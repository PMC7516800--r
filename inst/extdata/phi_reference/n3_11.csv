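0.00039455181131917367,0.00025331029298672123,2.5226564640512341e-06
0,0.0063937267341817438,0.64202035251032052
0.0099587602000186775,0,1
0,0,1
1,1,0
0.99004123979998138,1,0
1,0.9936062732658183,0.35797964748967948
0.9996054481886808,0.9997466897070133,0.99999747734353595
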