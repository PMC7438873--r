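effect,u0_A1,u1_A1,u0_A2,u1_A2,u0_A3,u1_A3
u0_A1,1,0.1,0.9,0.01,0.1,0.01
u1_A1,0.1,1,0.01,0.01,0.01,0.01
u0_A2,0.9,0.01,1,0.2,0.9,0.1
u1_A2,0.01,0.01,0.2,1,0.1,0.25
u0_A3,0.1,0.01,0.9,0.1,1,0.2
u1_A3,0.01,0.01,0.1,0.25,0.2,1
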