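trial,X1,X2,X3,X4,X5,X6,X7,growth_rate
1,1,1,-1,1,-1,-1,-1,0.222
2,-1,1,1,1,-1,1,1,0.267
3,-1,-1,-1,1,1,1,-1,0.282
4,1,-1,1,1,-1,1,-1,0.262
5,-1,-1,-1,-1,-1,-1,-1,0.124
6,-1,1,-1,-1,-1,1,1,0.102
7,-1,1,1,-1,1,-1,-1,0.217
8,1,-1,-1,-1,1,1,1,0.287
9,1,1,-1,1,1,-1,1,0.319
10,1,1,1,-1,1,1,-1,0.251
11,-1,-1,1,1,1,-1,1,0.305
12,1,-1,1,-1,-1,-1,1,0.196
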