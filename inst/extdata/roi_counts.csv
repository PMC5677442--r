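roi,samples,tp,fn,fp
1,6,5,1,0
2,9,4,5,1
3,1,1,0,0
4,2,1,1,0
5,13,11,2,3
6,2,2,0,0
7,9,7,2,0
8,2,2,0,0
9,3,3,0,1
10,2,2,0,0
11,4,3,1,0
12,2,1,1,0
13,7,4,3,1
14,1,1,0,0
15,6,4,2,0
16,6,5,1,0
17,7,5,2,0
18,6,3,3,0
19,1,1,0,0
20,7,4,3,1
21,4,3,1,1
22,7,5,2,1
23,3,3,0,0
24,8,6,2,0
25,1,1,0,0
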