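0000000000000000
0000000000000000
0000011111100000
0000111001110000
0001100000011000
0011000000001100
0011000000001100
0010000000000100
0010000000000100
0011000000001100
0011000000001100
0001100000011000
0000111001110000
0000011111100000
0000000000000000
0000000000000000
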