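case_id,index,value
r01,0,2.006769688790052e-03
r01,1,0.000000000000000e+00
r01,2,5.000000000000000e-01
r01,3,4.979932303112099e-01
r02,0,1.634731010925614e-07
r02,1,0.000000000000000e+00
r02,2,2.581658590878538e-01
r02,3,2.561470102400242e-01
r02,4,0.000000000000000e+00
r02,5,0.000000000000000e+00
r02,6,2.283637176277034e-01
r02,7,2.573232495713175e-01
r03,0,9.684288489703756e-01
r03,1,1.947321485595211e-03
r03,2,2.956438134083425e-02
r03,3,5.944820319484081e-05
r04,0,1.000000000000000e+00
r04,1,0.000000000000000e+00
r05,0,7.183826707655788e-01
r05,1,2.816173292344212e-01
r06,0,6.328718477085047e-01
r06,1,2.266728113501559e-01
r06,2,1.034154888931804e-01
r06,3,3.703985204815899e-02
r07,0,1.233470608080402e-02
r07,1,2.358666512911482e-01
r07,2,1.826508455972137e-01
r07,3,5.691477970308342e-01
r08,0,2.486957798649094e-08
r08,1,0.000000000000000e+00
r08,2,9.492949571037978e-03
r08,3,0.000000000000000e+00
r08,4,1.059832458604667e-05
r08,5,0.000000000000000e+00
r08,6,8.520578728663429e-01
r08,7,0.000000000000000e+00
r08,8,0.000000000000000e+00
r08,9,0.000000000000000e+00
r08,10,0.000000000000000e+00
r08,11,0.000000000000000e+00
r08,12,0.000000000000000e+00
r08,13,0.000000000000000e+00
r08,14,1.383622502507786e-01
r08,15,7.630411767628715e-05
r09,0,0.000000000000000e+00
r09,1,0.000000000000000e+00
r09,2,1.325466864049263e-02
r09,3,3.524276767937793e-02
r09,4,0.000000000000000e+00
r09,5,0.000000000000000e+00
r09,6,1.949854428863458e-01
r09,7,5.184457530315669e-01
r09,8,0.000000000000000e+00
r09,9,0.000000000000000e+00
r09,10,4.141538930239671e-03
r09,11,1.101191574926548e-02
r09,12,0.000000000000000e+00
r09,13,0.000000000000000e+00
r09,14,6.092493327798585e-02
r09,15,1.619929798047259e-01
r10,0,3.235401603759958e-02
r10,1,9.828282264772652e-02
r10,2,5.453353086187637e-02
r10,3,1.250000000000000e-01
r10,4,0.000000000000000e+00
r10,5,0.000000000000000e+00
r10,6,0.000000000000000e+00
r10,7,3.067930678234569e-02
r10,8,9.432069321765431e-02
r10,9,1.250000000000000e-01
r10,10,1.250000000000000e-01
r10,11,1.250000000000000e-01
r10,12,0.000000000000000e+00
r10,13,7.046646913812363e-02
r10,14,2.671717735227348e-02
r10,15,9.264598396240042e-02
r11,0,2.181610518894751e-01
r11,1,1.549166012303035e-01
r11,2,3.665993862261612e-01
r11,3,2.603229606540602e-01
r12,0,1.460336247107632e-01
r12,1,2.258873728359975e-01
r12,2,3.564537733399433e-01
r12,3,2.716252291132960e-01
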