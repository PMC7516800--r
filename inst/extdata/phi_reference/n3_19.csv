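0.33542746779735022,0.71647629845422367,0.43125290493800755
0,1,1
0.60190812434189789,0,0.46816268524307786
0,0.22220241543516606,1
1,0.77779758456483394,0
0.39809187565810211,1,0.5318373147569222
1,0,0
0.66457253220264978,0.28352370154577633,0.56874709506199239
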