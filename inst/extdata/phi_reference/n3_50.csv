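0.51154080931958212,0.75665996384893075,0.54415921386175248
0,1,1
0.71915951663909539,0,0.67605111114576244
0,0.05994275886773337,1
1,0.94005724113226663,0
0.28084048336090461,1,0.32394888885423756
1,0,0
0.48845919068041788,0.24334003615106925,0.45584078613824752
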