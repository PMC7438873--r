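item,parameter_type,attributes,value
1,intercept,NA,-1.5
1,main,A1,1.5
2,intercept,NA,-1.5
2,main,A2,1.5
3,intercept,NA,-1.5
3,main,A3,1.5
4,intercept,NA,-1.5
4,main,A1,1.5
4,main,A2,1.5
4,interaction,A1:A2,0.5
5,intercept,NA,-1.5
5,main,A1,1.5
5,main,A3,1.5
5,interaction,A1:A3,0.5
6,intercept,NA,-1.5
6,main,A2,1.5
6,main,A3,1.5
6,interaction,A2:A3,0.5
7,intercept,NA,-1.5
7,main,A1,1.5
8,intercept,NA,-1.5
8,main,A2,1.5
9,intercept,NA,-1.5
9,main,A3,1.5
10,intercept,NA,-1.5
10,main,A1,1.5
10,main,A2,1.5
10,interaction,A1:A2,0.5
11,intercept,NA,-1.5
11,main,A1,1.5
11,main,A3,1.5
11,interaction,A1:A3,0.5
12,intercept,NA,-1.5
12,main,A2,1.5
12,main,A3,1.5
12,interaction,A2:A3,0.5
13,intercept,NA,-1.5
13,main,A1,1.5
14,intercept,NA,-1.5
14,main,A2,1.5
15,intercept,NA,-1.5
15,main,A3,1.5
16,intercept,NA,-1.5
16,main,A1,1.5
16,main,A2,1.5
16,interaction,A1:A2,0.5
17,intercept,NA,-1.5
17,main,A1,1.5
17,main,A3,1.5
17,interaction,A1:A3,0.5
18,intercept,NA,-1.5
18,main,A2,1.5
18,main,A3,1.5
18,interaction,A2:A3,0.5
19,intercept,NA,-1.5
19,main,A1,1.5
20,intercept,NA,-1.5
20,main,A2,1.5
21,intercept,NA,-1.5
21,main,A3,1.5
22,intercept,NA,-1.5
22,main,A1,1.5
22,main,A2,1.5
22,interaction,A1:A2,0.5
23,intercept,NA,-1.5
23,main,A1,1.5
23,main,A3,1.5
23,interaction,A1:A3,0.5
24,intercept,NA,-1.5
24,main,A2,1.5
24,main,A3,1.5
24,interaction,A2:A3,0.5
25,intercept,NA,-1.5
25,main,A1,1.5
26,intercept,NA,-1.5
26,main,A2,1.5
27,intercept,NA,-1.5
27,main,A3,1.5
28,intercept,NA,-1.5
28,main,A1,1.5
28,main,A2,1.5
28,interaction,A1:A2,0.5
29,intercept,NA,-1.5
29,main,A1,1.5
29,main,A3,1.5
29,interaction,A1:A3,0.5
30,intercept,NA,-1.5
30,main,A2,1.5
30,main,A3,1.5
30,interaction,A2:A3,0.5
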