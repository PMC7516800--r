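0.24400933036707939,0.28140360384913815,0.080131745587586539
0,0.32839623577934107,1
0.2847573538203354,0,0.86711515783534165
0,0,1
1,1,0
0.7152426461796646,1,0.13288484216465835
1,0.67160376422065893,0
0.75599066963292061,0.7185963961508619,0.91986825441241349
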