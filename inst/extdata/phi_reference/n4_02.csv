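0.018869167909588522,0.02531627533715405,0.0098281952070049163,0.069054611180013506
0,0.35102830000707869,0.53660127646708378,0.25619281044954845
0.26163453531926933,0,0.19095009408857805,0.39994902296299512
0,0,1,1
1,0.49186499207468326,0,0.67393980220601291
0.029335104945092061,1,0,1
1,0,0,1
0.92999533159342351,0.85337373691436436,0.90408154038280852,1
0.070004668406576501,0.14662626308563562,0.095918459617191448,0
0,1,1,0
0.97066489505490794,0,1,0
0,0.50813500792531674,1,0.32606019779398709
1,1,0,0
0.73836546468073072,1,0.80904990591142201,0.60005097703700483
1,0.64897169999292137,0.46339872353291622,0.74380718955045155
0.98113083209041152,0.97468372466284592,0.99017180479299505,0.93094538881998645
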