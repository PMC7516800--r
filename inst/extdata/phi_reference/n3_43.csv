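0.088014940404880351,0.1590312297174164,0.12554730642480252
0,1,1
0.78945064216561966,0,0.55344438046083555
0,0.29894999015691726,1
1,0.70105000984308274,0
0.21054935783438034,1,0.44655561953916445
1,0,0
0.91198505959511966,0.84096877028258366,0.8744526935751975
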