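MEME version 4

ALPHABET= ACGT

Background letter frequencies
A 0.25 C 0.25 G 0.25 T 0.25

MOTIF JUN_syn
letter-probability matrix: alength= 4 w= 11 nsites= 20 E= 0
0.150000 0.150000 0.550000 0.150000
0.050000 0.850000 0.050000 0.050000
0.050000 0.050000 0.050000 0.850000
0.050000 0.050000 0.850000 0.050000
0.850000 0.050000 0.050000 0.050000
0.050000 0.050000 0.850000 0.050000
0.050000 0.050000 0.050000 0.850000
0.050000 0.850000 0.050000 0.050000
0.850000 0.050000 0.050000 0.050000
0.050000 0.050000 0.050000 0.850000
0.150000 0.150000 0.550000 0.150000

MOTIF DBP_syn
letter-probability matrix: alength= 4 w= 11 nsites= 20 E= 0
0.550000 0.150000 0.150000 0.150000
0.050000 0.050000 0.050000 0.850000
0.050000 0.050000 0.050000 0.850000
0.850000 0.050000 0.050000 0.050000
0.050000 0.050000 0.050000 0.850000
0.050000 0.050000 0.850000 0.050000
0.050000 0.050000 0.050000 0.850000
0.850000 0.050000 0.050000 0.050000
0.850000 0.050000 0.050000 0.050000
0.050000 0.850000 0.050000 0.050000
0.150000 0.550000 0.150000 0.150000

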