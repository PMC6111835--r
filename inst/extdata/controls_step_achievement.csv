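control,right_step,left_step
1,80,72
2,88,80
3,84,80
4,76,84
5,80,72
6,72,64
7,72,68
8,80,76
9,68,76
10,80,84
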