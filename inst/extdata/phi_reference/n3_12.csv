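0.024726059798433692,0.032661226743521649,0.0089003107052625548
0,0.35995669256718199,1
0.27250387057271008,0,0.75704626750855653
0,0,1
1,1,0
0.72749612942728992,1,0.24295373249144347
1,0.64004330743281801,0
0.97527394020156633,0.96733877325647832,0.99109968929473746
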