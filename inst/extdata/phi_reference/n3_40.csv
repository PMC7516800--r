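0.46407505496443591,0.54551752433410605,0.43244014056441571
0,0.93183233172822766,1
0.79271539643438604,0,0.85070604382676052
0,0,1
1,1,0
0.20728460356561396,1,0.14929395617323948
1,0.068167668271772341,0
0.53592494503556409,0.45448247566589395,0.56755985943558429
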