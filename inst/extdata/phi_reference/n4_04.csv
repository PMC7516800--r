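0.22249650905607235,0.22732247396600497,0.51532214045336588,0.31862142500842322
0,0.99531158555401233,1,0.52892891452083146
0.97418151995807234,0,0.51769996589647327,1
0,0,1,1
0.61835486202439105,0.2283713968046607,0,0.42973770351493851
0,0.99990420253310786,0.30175695357513721,0.71338798714751306
1,0,0,1
0.63064367998294046,0,0.30496402367487507,1
0.36935632001705954,1,0.69503597632512493,0
0,1,1,0
1,9.5797466892144634e-05,0.69824304642486279,0.28661201285248694
0.38164513797560895,0.77162860319533932,1,0.57026229648506144
1,1,0,0
0.025818480041927661,1,0.48230003410352673,0
1,0.0046884144459876653,0,0.47107108547916854
0.77750349094392768,0.77267752603399509,0.48467785954663412,0.68137857499157684
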