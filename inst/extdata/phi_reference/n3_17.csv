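0.034058068932619451,0.017472337867722187,0.088316825227872459
0,1,0.51301610500259087
1,0,1
0.80216297605081965,0.61436488636515374,1
0.19783702394918032,0.38563511363484626,0
0,1,0
1,0,0.48698389499740913
0.96594193106738058,0.98252766213227782,0.91168317477212757
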