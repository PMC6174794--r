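# 120 kVp tungsten-anode x-ray spectrum, 1 keV bins
# Kramers bremsstrahlung continuum hardened by 7 mm Al-equivalent total
# filtration, plus W K-fluorescence lines (Ka1/Ka2/Kb) at 7% of total
# fluence. Normalized to unit sum. Columns: energy_keV relative_fluence
10 0
11 0
12 6.11565e-14
13 2.44789e-11
14 1.99991e-09
15 5.44679e-08
16 6.64733e-07
17 4.65257e-06
18 2.15726e-05
19 7.3347e-05
20 0.000196701
21 0.000419609
22 0.000784818
23 0.00132136
24 0.00204362
25 0.00294943
26 0.00402164
27 0.00523181
28 0.00654471
29 0.00792252
30 0.00932831
31 0.0104771
32 0.0115849
33 0.0126372
34 0.0136235
35 0.0145361
36 0.0153702
37 0.0161233
38 0.0167948
39 0.0173854
40 0.0178973
41 0.0181345
42 0.0183186
43 0.0184532
44 0.0185419
45 0.0185881
46 0.0185952
47 0.0185664
48 0.0185048
49 0.0184132
50 0.0182944
51 0.0180535
52 0.0178008
53 0.0175376
54 0.0172653
55 0.0169849
56 0.0166977
57 0.0164046
58 0.0354655
59 0.0491819
60 0.0154982
61 0.0151339
62 0.0147731
63 0.0144159
64 0.0140625
65 0.0137128
66 0.013367
67 0.0230385
68 0.0126873
69 0.0150236
70 0.0120235
71 0.0116977
72 0.0113759
73 0.0110582
74 0.0107445
75 0.0104348
76 0.0101291
77 0.00982733
78 0.00952953
79 0.00923564
80 0.00894562
81 0.00864513
82 0.00834988
83 0.00805973
84 0.00777454
85 0.00749421
86 0.0072186
87 0.0069476
88 0.00668109
89 0.00641897
90 0.00616113
91 0.00590746
92 0.00565788
93 0.00541227
94 0.00517055
95 0.00493263
96 0.00469841
97 0.00446782
98 0.00424076
99 0.00401716
100 0.00379695
101 0.00357737
102 0.00336139
103 0.00314894
104 0.00293991
105 0.00273422
106 0.0025318
107 0.00233255
108 0.00213641
109 0.0019433
110 0.00175315
111 0.00156589
112 0.00138144
113 0.00119976
114 0.00102076
115 0.000844394
116 0.000670599
117 0.000499317
118 0.000330492
119 0.000164071
120 0
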