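3.3141315675565528e-05,1.8035273207663522e-06,3.690503003632007e-05
0,1,0.054419303639657801
1,0,1
0.9511305824980657,0.10198377719921958,1
0.048869417501934263,0.89801622280078042,0
0,1,0
1,0,0.94558069636034214
0.99996685868432444,0.99999819647267918,0.99996309496996372
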