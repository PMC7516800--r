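0.00018476374384543244,0.00031642417822054189,2.7737020986372059e-06
0,0.015012155745001551,1
0.0087657716747042841,0,0.58391158629052564
0,0,1
1,1,0
0.99123422832529573,1,0.41608841370947436
1,0.98498784425499841,0
0.99981523625615454,0.99968357582177947,0.99999722629790133
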