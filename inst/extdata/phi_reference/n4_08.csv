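0.14672968963484287,0.23754074159341956,0.16728617174340388,0.13344442494818876
0,1,0.25527634353277429,0.6872435773340424
0.86720389113006524,0,0.424512595731311,0.15768502870885676
0,0.28770700544256478,0.64780024608440978,0.81208355661145781
0.22390744116695593,0.60279361859292024,0,1
0,1,0,1
1,0,0,1
0.24433683276828533,0.71930922800091168,0,1
0.75566316723171467,0.28069077199908832,1,0
0,1,1,0
1,0,1,0
0.77609255883304407,0.39720638140707976,1,0
1,0.71229299455743522,0.35219975391559022,0.18791644338854219
0.13279610886993476,1,0.57548740426868905,0.8423149712911433
1,0,0.74472365646722571,0.3127564226659576
0.8532703103651571,0.76245925840658046,0.83271382825659612,0.86655557505181124
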