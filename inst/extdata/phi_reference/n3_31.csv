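4.3772204963410138e-06,0.0028199482938220267,0.0010433971089597498
0,1,1
0.37000575905793592,0,0.0015522343107959363
0,0.9958048374307793,1
1,0.0041951625692206729,0
0.62999424094206402,1,0.99844776568920401
1,0,0
0.99999562277950371,0.99718005170617796,0.99895660289104027
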