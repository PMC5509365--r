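000000100000000000000010000000
000001110000000000000111000000
000000110000000000000110000000
000000111000000000001110000000
000000111000000000001110000000
000000011100000000011100000000
000000011100000000011100000000
000000001110000000111000000000
000000001110000000111000000000
000000000111000001110000000000
000000000111000001110000000000
000000000011100011100000000000
000000000011100011100000000000
000000000001110111000000000000
000000000001110111000000000000
000000000000111110000000000000
000000000000111110000000000000
000000000000011100000000000000
000000000000011100000000000000
000000000000001000000000000000
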