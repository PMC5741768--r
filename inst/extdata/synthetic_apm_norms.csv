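percentile,raw
1,5
5,8
10,11
25,16
50,21
75,26
90,30
95,33
99,36
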