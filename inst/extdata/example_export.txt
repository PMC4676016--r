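Planning system DVH export (synthetic example)
Structure: GTV
Total Volume: 4.9 cc
0.0    100.0 %
24.0   100.0 %
48.0   100.0 %
54.0   45.0 %
60.0   0.0 %
Structure: Lung
Total Volume: 3200 cc
0.0    3200
5.0    1100
10.0   390
20.0   48
40.0   0
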