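cft_raw,age_lo,age_hi,iq
10,15,39,60
15,15,39,70
20,15,39,80
25,15,39,90
30,15,39,100
35,15,39,110
40,15,39,120
45,15,39,130
50,15,39,140
10,40,70,66
15,40,70,76
20,40,70,86
25,40,70,96
30,40,70,106
35,40,70,116
40,40,70,126
45,40,70,136
50,40,70,146
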