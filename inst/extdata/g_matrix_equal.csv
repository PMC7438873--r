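effect,u0_A1,u1_A1,u0_A2,u1_A2,u0_A3,u1_A3
u0_A1,0.15000000000000002,0.017320508075688773,0.13500000000000004,0.008660254037844387,0.13500000000000004,0.008660254037844387
u1_A1,0.017320508075688773,0.049999999999999996,0.008660254037844387,0.012499999999999999,0.008660254037844387,0.012499999999999999
u0_A2,0.13500000000000004,0.008660254037844387,0.15000000000000002,0.017320508075688773,0.13500000000000004,0.008660254037844387
u1_A2,0.008660254037844387,0.012499999999999999,0.017320508075688773,0.049999999999999996,0.008660254037844387,0.012499999999999999
u0_A3,0.13500000000000004,0.008660254037844387,0.13500000000000004,0.008660254037844387,0.15000000000000002,0.017320508075688773
u1_A3,0.008660254037844387,0.012499999999999999,0.008660254037844387,0.012499999999999999,0.017320508075688773,0.049999999999999996
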