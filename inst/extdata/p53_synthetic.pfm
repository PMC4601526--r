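>p53_synthetic synthetic p53-like dimeric response element (RRRCWWGYYY x2)
A [ 40 40 40  3 45 45  3  3  4  4 40 40 40  3 45 45  3  3  4  4 ]
C [  4  4  4 91  4  4  3 50 50 50  4  4  4 91  4  4  3 50 50 50 ]
G [ 52 52 52  3  3  3 91  5  4  4 52 52 52  3  3  3 91  5  4  4 ]
T [  4  4  4  3 48 48  3 42 42 42  4  4  4  3 48 48  3 42 42 42 ]
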