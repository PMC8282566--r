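age,qx
65,0.00347
70,0.00602
75,0.01072
80,0.02092
85,0.04694
90,0.10511
95,0.19900
100,0.33677
105,0.51025
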