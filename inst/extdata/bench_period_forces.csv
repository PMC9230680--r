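period,F1,F2,Fz2m
1,0.56,8.56,5.26
2,12.18,20.78,11.03
3,16.89,30.31,15.58
4,27.28,40.03,48.11
5,35.81,53.04,59.75
6,43.17,63.83,72.83
7,58.65,77.15,93.52
8,70.51,91.92,111.37
9,90.77,99.39,130.25
10,99.62,117.54,145.39
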