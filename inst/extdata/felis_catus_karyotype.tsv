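A1	240000000
A2	171000000
A3	143000000
B1	208000000
B2	155000000
B3	149000000
B4	144000000
C1	222000000
C2	161000000
D1	117000000
D2	90000000
D3	96000000
D4	96000000
E1	63000000
E2	64000000
E3	43000000
F1	71000000
F2	85000000
X	131000000
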