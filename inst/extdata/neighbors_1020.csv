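channel,neighbor
Fp1,Fp2
Fp1,F3
Fp1,Fz
Fp2,Fp1
Fp2,F4
Fp2,Fz
F3,Fp1
F3,Fz
F3,C3
F4,Fp2
F4,Fz
F4,C4
Fz,F3
Fz,F4
C3,F3
C3,Cz
C3,P3
C4,F4
C4,Cz
C4,P4
Cz,C3
Cz,C4
P3,C3
P3,O1
P4,C4
P4,O2
O1,P3
O1,O2
O2,P4
O2,O1
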