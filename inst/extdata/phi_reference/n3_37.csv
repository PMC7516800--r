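0.0077936657615795477,0.010129343344718105,0.011716434757312323
0,1,1
1,0,0.7694147089646749
0.1354585627341709,0.33480910165821032,1
0.8645414372658291,0.66519089834178968,0
0,1,0.2305852910353251
1,0,0
0.99220633423842042,0.98987065665528184,0.98828356524268768
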