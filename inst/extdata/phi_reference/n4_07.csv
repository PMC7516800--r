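0.044740195216335613,0.083147987678593854,0.018685307146361747,0.10618799453997321
0,1,0.23151578821580174,0.14702640139373063
1,0,0.079111835222493376,0.1245738092962342
0.23246505863831812,0.58700548178484691,0.98021609948758348,0.17248314150842614
0.55434259010591769,0.35204076918755073,0,1
0,1,0,1
1,0,0,1
0.93805335594849548,0.90245543664976546,0,1
0.061946644051504525,0.097544563350234592,1,0
0,1,1,0
1,0,1,0
0.44565740989408231,0.64795923081244933,1,0
0.76753494136168188,0.41299451821515309,0.019783900512416519,0.82751685849157386
0,1,0.92088816477750668,0.87542619070376582
1,0,0.76848421178419823,0.85297359860626942
0.95525980478366435,0.91685201232140612,0.98131469285363826,0.89381200546002681
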