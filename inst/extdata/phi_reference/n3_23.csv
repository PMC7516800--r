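0.15547105165691638,0.2064295189454344,0.46189148406816893
0,1,1
1,0,0.75314350607972969
0.55307788503204325,0.66340351138846509,1
0.44692211496795675,0.33659648861153496,0
0,1,0.24685649392027031
1,0,0
0.84452894834308356,0.79357048105456562,0.53810851593183107
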