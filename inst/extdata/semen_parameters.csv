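subject,age,concentration,motility,progressive_motility,normal_forms
1,32,125,96,80,4
2,33,60,87,80,4
3,43,137,80,76,6
4,48,133,98,92,5
5,30,70,91,87,5
6,42,66,68,60,10
7,29,92,78,60,6
8,38,48,73,57,4
9,29,50,90,66,4
10,35,48,59,54,4
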