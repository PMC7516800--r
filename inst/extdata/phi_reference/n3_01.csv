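0.0002071104024022565,2.3908403427427199e-05,0.0030573529647335662
0,1,0.1154379652113828
1,0,1
0.992180031647242,0.9322582623624861,1
0.0078199683527579496,0.067741737637513885,0
0,1,0
1,0,0.88456203478861717
0.99979288959759771,0.99997609159657252,0.99694264703526647
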