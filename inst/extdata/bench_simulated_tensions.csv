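period,Fz2s
1,3.667
2,22.32
3,32.71
4,50.89
5,68.53
6,81.28
7,120.00
8,130.60
9,151.31
10,155.0
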