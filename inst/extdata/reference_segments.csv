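segment,roundness,critical_point,is_background
1,0.654,FALSE,TRUE
2,0.761,TRUE,FALSE
3,0.16,FALSE,FALSE
4,0.352,FALSE,FALSE
5,0.26,FALSE,FALSE
6,0.26,FALSE,FALSE
7,0.911,TRUE,FALSE
8,0.785,TRUE,FALSE
9,0.877,TRUE,FALSE
10,0.771,TRUE,FALSE
11,0.357,FALSE,FALSE
12,0.748,FALSE,FALSE
13,0.208,FALSE,FALSE
14,0.749,TRUE,FALSE
15,0.907,TRUE,FALSE
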