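0.072999469486550977,0.10787024285877091,0.10267467436116148
0,1,1
0.95183501622025901,0,0.67673407931532614
0,0.28902166049465161,1
1,0.71097833950534839,0
0.048164983779740989,1,0.32326592068467386
1,0,0
0.92700053051344899,0.89212975714122911,0.89732532563883849
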