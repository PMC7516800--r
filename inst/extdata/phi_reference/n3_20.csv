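0.56701075284460434,0.58015313818789782,0.37640628718184876
0,0.66384329625757044,1
0.64880505233075147,0,0.97734669610795588
0,0,1
1,1,0
0.35119494766924853,1,0.022653303892044119
1,0.33615670374242956,0
0.43298924715539566,0.41984686181210218,0.62359371281815124
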