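category_lo_um,category_hi_um,fraction
0,25,0.000015
25,50,0.033931
50,75,0.161396
75,100,0.223000
100,125,0.197140
125,150,0.142814
150,175,0.093832
175,200,0.058680
200,225,0.035824
225,250,0.021654
250,275,0.013065
275,300,0.007908
300,325,0.004815
325,350,0.002954
350,375,0.001829
375,400,0.001142
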