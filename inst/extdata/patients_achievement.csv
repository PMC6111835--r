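patient,right_knee,left_knee,right_step,left_step
1,100,100,64,56
2,92,96,52,60
3,100,100,80,76
4,72,76,68,64
5,100,100,64,56
6,60,52,52,56
7,64,60,68,72
8,100,100,80,76
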