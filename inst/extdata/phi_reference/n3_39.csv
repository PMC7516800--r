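0.23455113874361036,0.32365246609572462,0.27859300234111606
0,1,1
0.86077824680847126,0,0.72470060733057617
0,0.15808675461122956,1
1,0.84191324538877044,0
0.13922175319152874,1,0.27529939266942383
1,0,0
0.76544886125638967,0.67634753390427538,0.72140699765888394
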