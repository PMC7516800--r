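0.00018073330121798627,4.339884117044208e-06,0.00048429435468127797
0,1,0.024012642317697619
1,0,1
0.99103874725134811,0.62681105102509493,1
0.0089612527486518916,0.37318894897490507,0
0,1,0
1,0,0.97598735768230238
0.99981926669878196,0.99999566011588292,0.99951570564531877
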