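0.00072123271436295208,3.0931185019619395e-06,0.0013774158257197167
0,1,0.0042886552985800406
1,0,1
0.9977544047017568,0.47638708595053425,1
0.0022455952982431775,0.52361291404946575,0
0,1,0
1,0,0.99571134470141998
0.99927876728563703,0.999996906881498,0.99862258417428029
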