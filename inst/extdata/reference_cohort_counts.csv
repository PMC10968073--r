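group,animals,has_left,has_right,non_left,non_right
G1,7,470,538,2213,2212
G2,14,594,709,4423,4437
G3,5,0,0,2438,2457
G4,14,844,800,4443,4437
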