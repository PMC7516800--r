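0.067834758448488311,0.036529015107823963,0.36775844579020073
0,1,0.53849996584808368
1,0,1
0.90067117281471476,0.81554534171817017,1
0.099328827185285296,0.18445465828182983,0
0,1,0
1,0,0.46150003415191632
0.9321652415515117,0.96347098489217609,0.63224155420979922
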