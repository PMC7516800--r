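0.0072526861387907813,0.062501649704756523,0.067276404597241685
0,1,1
1,0,0.11603991531504874
0.070972206690738671,0.89219569353906669,1
0.92902779330926133,0.10780430646093331,0
0,1,0.88396008468495124
1,0,0
0.99274731386120918,0.93749835029524342,0.93272359540275829
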