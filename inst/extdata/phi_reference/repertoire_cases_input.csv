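"case_id","tpm_path","state_code","direction","mechanism","purview"
"r01","inst/extdata/phi_reference/n3_01.csv",5,"cause","1","1;2"
"r02","inst/extdata/phi_reference/n3_01.csv",5,"cause","1;3","1;2;3"
"r03","inst/extdata/phi_reference/n3_01.csv",5,"effect","2","1;3"
"r04","inst/extdata/phi_reference/n3_01.csv",5,"effect","1;2;3","3"
"r05","inst/extdata/phi_reference/n3_02.csv",2,"cause","2;3","2"
"r06","inst/extdata/phi_reference/n3_02.csv",2,"effect","1;2","2;3"
"r07","inst/extdata/phi_reference/n4_01.csv",9,"cause","1;4","2;3"
"r08","inst/extdata/phi_reference/n4_01.csv",9,"cause","1;2;3;4","1;2;3;4"
"r09","inst/extdata/phi_reference/n4_01.csv",9,"effect","2;4","1;2;3;4"
"r10","inst/extdata/phi_reference/n4_05.csv",12,"cause","3","1;2;3;4"
"r11","inst/extdata/phi_reference/n4_05.csv",12,"effect","1;3","2;4"
"r12","inst/extdata/phi_reference/n4_05.csv",12,"cause","2;3","1;4"
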