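frequency_khz,mean_printed,sd_printed
20,80,9
25,63,7
30,57.5,4.63
35,53,4
40,57.5,7.07
45,58,6.6
50,55,5.77
55,59,7.5
60,58.8,3.54
65,60,5.77
70,62.1,10.4
75,59,9.7
80,57,5.7
85,58.6,7.48
90,57.1,4.88
95,58.3,6.06
100,60,8.7
105,56,5.3
110,59,7.9
115,58,7
120,58,6.4
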