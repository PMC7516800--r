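0.080416439250586669,0.027865212300949755,0.33256734618247508
0,1,0.34651139195704278
1,0,1
0.9162118210918383,0.75819502373373937,1
0.083788178908161662,0.24180497626626066,0
0,1,0
1,0,0.65348860804295716
0.91958356074941339,0.97213478769905026,0.66743265381752492
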