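age,first_breeding_pct
5,1
6,7
7,21
8,39
9,54
10,67
11,78
12,86
13,91
14,94
15,96
16,100
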