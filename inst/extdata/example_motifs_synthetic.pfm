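>SYN0001.1 synthetic_zf_like
A [ 12   2   0  80   1   3  70   5 ]
C [ 60   4  78   2   1  75   6   8 ]
G [ 20  88   2  10  90   4  14  12 ]
T [  8   6  20   8   8  18  10  75 ]
>SYN0002.1 synthetic_at_rich
A 40 55 60 10 48
C 10  5  8  6 12
G  8  6  7  4 10
T 42 34 25 80 30
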