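0.24995482845546141,0.28865181506034565,0.35736086800009215
0,1,1
1,0,0.8659388765776711
0.19226798201007489,0.30055344376598903,1
0.80773201798992511,0.69944655623401097,0
0,1,0.1340611234223289
1,0,0
0.75004517154453865,0.71134818493965435,0.64263913199990785
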