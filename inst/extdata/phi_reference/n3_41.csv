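3.0825000603301104e-05,0.00014740665003067031,0.002805519310542686
0,1,1
1,0,0.20911540013213445
0.94745833704414717,0.98901272912737903,1
0.052541662955852858,0.010987270872620922,0
0,1,0.79088459986786552
1,0,0
0.99996917499939675,0.99985259334996934,0.99719448068945726
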