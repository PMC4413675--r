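0000000000000000
0111111111111100
0100000000000100
0100000000000100
0100000000000100
0100000000000100
0100000000000100
0100000000000100
0100000000000100
0100000000000100
0100000000000100
0100000000000100
0100000000000100
0111111111111100
0000000000000000
0000000000000000
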