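"case_id","n","net_seed","temperature","state_code","phi"
"n3_01",3,201,0.3,3,0.165764669324
"n3_02",3,202,0.8,6,0.115875463733
"n3_03",3,203,1.5,1,0.589165971065
"n3_04",3,204,2.5,4,0.079825550655
"n3_05",3,205,4,7,0.350965559683
"n3_06",3,206,0.3,2,0.616081263469
"n3_07",3,207,0.8,5,0.758828795082
"n3_08",3,208,1.5,0,0.384446291257
"n3_09",3,209,2.5,3,0.662305397414
"n3_10",3,210,4,6,0.222917499638
"n3_11",3,211,0.3,1,0.591955311058
"n3_12",3,212,0.8,4,0.745588691018
"n3_13",3,213,1.5,7,0.417240328083
"n3_14",3,214,2.5,2,0.459606390879
"n3_15",3,215,4,5,0.220121105624
"n3_16",3,216,0.3,0,0.107383442211
"n3_17",3,217,0.8,3,0.720244259037
"n3_18",3,218,1.5,6,0.577983437477
"n3_19",3,219,2.5,1,0.221384987866
"n3_20",3,220,4,4,0.425211704027
"n3_21",3,221,0.3,7,0.190333935156
"n3_22",3,222,0.8,2,0.31896567686
"n3_23",3,223,1.5,5,0.235321314555
"n3_24",3,224,2.5,0,0.511470685319
"n3_25",3,225,4,3,0.116070840709
"n3_26",3,226,0.3,6,0.301845098711
"n3_27",3,227,0.8,1,0.06505675184
"n3_28",3,228,1.5,4,0.576274518988
"n3_29",3,229,2.5,7,0.459121249108
"n3_30",3,230,4,2,0.328149803335
"n3_31",3,231,0.3,5,0.607198468693
"n3_32",3,232,0.8,0,0.316429062568
"n3_33",3,233,1.5,3,0.6126285961
"n3_34",3,234,2.5,6,0.580786076876
"n3_35",3,235,4,1,0.29079762176
"n3_36",3,236,0.3,4,0.028321476261
"n3_37",3,237,0.8,7,1.282939757887
"n3_38",3,238,1.5,2,0.579564057213
"n3_39",3,239,2.5,5,0.333285705388
"n3_40",3,240,4,0,0.439585859236
"n3_41",3,241,0.3,3,0.165838045828
"n3_42",3,242,0.8,6,0.136115231381
"n3_43",3,243,1.5,1,0.620571686595
"n3_44",3,244,2.5,4,0.306873111326
"n3_45",3,245,4,7,0.441355635251
"n3_46",3,246,0.3,2,0.263186937078
"n3_47",3,247,0.8,5,0.977232309111
"n3_48",3,248,1.5,0,0.324925706735
"n3_49",3,249,2.5,3,0.363065638333
"n3_50",3,250,4,6,0.228927316059
"n4_01",4,301,0.5,5,1.616558186002
"n4_02",4,302,1,10,2.941524122965
"n4_03",4,303,1.8,15,2.180135272098
"n4_04",4,304,2.7,4,0.746934989654
"n4_05",4,305,3.6,9,0.984614805058
"n4_06",4,306,0.5,14,1.440307745502
"n4_07",4,307,1,3,2.09886930339
"n4_08",4,308,1.8,8,0.982759442975
"n4_09",4,309,2.7,13,0.778685724665
"n4_10",4,310,3.6,2,0.917252373161
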