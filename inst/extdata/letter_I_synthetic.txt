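000000000111111111110000000000
000000001111111111111000000000
000000000111111111110000000000
000000000000011100000000000000
000000000000011100000000000000
000000000000011100000000000000
000000000000011100000000000000
000000000000011100000000000000
000000000000011100000000000000
000000000000011100000000000000
000000000000011100000000000000
000000000000011100000000000000
000000000000011100000000000000
000000000000011100000000000000
000000000000011100000000000000
000000000000011100000000000000
000000000000011100000000000000
000000000111111111110000000000
000000001111111111111000000000
000000000111111111110000000000
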