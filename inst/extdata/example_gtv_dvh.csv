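# synthetic example: cumulative GTV DVH of a 48 Gy plan, 4 Gy grid
# scale: physical
dose,volume_cc
0,4.9
4,4.9
8,4.9
12,4.9
16,4.9
20,4.9
24,4.9
28,4.9
32,4.9
36,4.9
40,4.9
44,4.9
48,4.9
52,3.2
56,1.1
60,0
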