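0.40128674554317939,0.4489351668437126,0.8922973702169873
0,1,1
1,0,0.89386346889344703
0.49687718262069813,0.55027689317789297,1
0.50312281737930187,0.44972310682210703,0
0,1,0.10613653110655297
1,0,0
0.59871325445682055,0.5510648331562874,0.1077026297830127
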