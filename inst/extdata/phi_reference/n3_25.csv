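0.83269705814506434,0.58179762725262574,0.52652694694214697
0,0.63231512804314549,0.69869062411323035
0.90500016204693212,0,1
0,0,1
1,1,0
0.094999837953067878,1,0
1,0.36768487195685451,0.30130937588676965
0.16730294185493566,0.41820237274737426,0.47347305305785303
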