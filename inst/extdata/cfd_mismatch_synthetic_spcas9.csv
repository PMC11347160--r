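# SYNTHETIC model CFD mismatch factors for SpCas9 (and SpCas9-VQR); not measured data.
# position 1 = PAM-distal end of the 20-nt spacer; guide_base = spacer base,
# site_base = protospacer-strand base observed at the (off-)target site.
position,guide_base,site_base,factor
1,A,C,0.665
1,A,G,0.8075
1,A,T,0.5225
1,C,A,0.57
1,C,G,0.475
1,C,T,0.7125
1,G,A,0.855
1,G,C,0.5225
1,G,T,0.76
1,T,A,0.6175
1,T,C,0.8075
1,T,G,0.9025
2,A,C,0.6355
2,A,G,0.7717
2,A,T,0.4993
2,C,A,0.5447
2,C,G,0.4539
2,C,T,0.6809
2,G,A,0.8171
2,G,C,0.4993
2,G,T,0.7263
2,T,A,0.5901
2,T,C,0.7717
2,T,G,0.8625
3,A,C,0.6061
3,A,G,0.7359
3,A,T,0.4762
3,C,A,0.5195
3,C,G,0.4329
3,C,T,0.6493
3,G,A,0.7792
3,G,C,0.4762
3,G,T,0.6926
3,T,A,0.5628
3,T,C,0.7359
3,T,G,0.8225
4,A,C,0.5766
4,A,G,0.7001
4,A,T,0.453
4,C,A,0.4942
4,C,G,0.4118
4,C,T,0.6178
4,G,A,0.7413
4,G,C,0.453
4,G,T,0.6589
4,T,A,0.5354
4,T,C,0.7001
4,T,G,0.7825
5,A,C,0.5471
5,A,G,0.6643
5,A,T,0.4299
5,C,A,0.4689
5,C,G,0.3908
5,C,T,0.5862
5,G,A,0.7034
5,G,C,0.4299
5,G,T,0.6253
5,T,A,0.508
5,T,C,0.6643
5,T,G,0.7425
6,A,C,0.5176
6,A,G,0.6286
6,A,T,0.4067
6,C,A,0.4437
6,C,G,0.3697
6,C,T,0.5546
6,G,A,0.6655
6,G,C,0.4067
6,G,T,0.5916
6,T,A,0.4807
6,T,C,0.6286
6,T,G,0.7025
7,A,C,0.4882
7,A,G,0.5928
7,A,T,0.3836
7,C,A,0.4184
7,C,G,0.3487
7,C,T,0.523
7,G,A,0.6276
7,G,C,0.3836
7,G,T,0.5579
7,T,A,0.4533
7,T,C,0.5928
7,T,G,0.6625
8,A,C,0.4587
8,A,G,0.557
8,A,T,0.3604
8,C,A,0.3932
8,C,G,0.3276
8,C,T,0.4914
8,G,A,0.5897
8,G,C,0.3604
8,G,T,0.5242
8,T,A,0.4259
8,T,C,0.557
8,T,G,0.6225
9,A,C,0.4292
9,A,G,0.5212
9,A,T,0.3372
9,C,A,0.3679
9,C,G,0.3066
9,C,T,0.4599
9,G,A,0.5518
9,G,C,0.3372
9,G,T,0.4905
9,T,A,0.3986
9,T,C,0.5212
9,T,G,0.5825
10,A,C,0.3997
10,A,G,0.4854
10,A,T,0.3141
10,C,A,0.3426
10,C,G,0.2855
10,C,T,0.4283
10,G,A,0.5139
10,G,C,0.3141
10,G,T,0.4568
10,T,A,0.3712
10,T,C,0.4854
10,T,G,0.5425
11,A,C,0.3703
11,A,G,0.4496
11,A,T,0.2909
11,C,A,0.3174
11,C,G,0.2645
11,C,T,0.3967
11,G,A,0.4761
11,G,C,0.2909
11,G,T,0.4232
11,T,A,0.3438
11,T,C,0.4496
11,T,G,0.5025
12,A,C,0.3408
12,A,G,0.4138
12,A,T,0.2678
12,C,A,0.2921
12,C,G,0.2434
12,C,T,0.3651
12,G,A,0.4382
12,G,C,0.2678
12,G,T,0.3895
12,T,A,0.3164
12,T,C,0.4138
12,T,G,0.4625
13,A,C,0.3113
13,A,G,0.378
13,A,T,0.2446
13,C,A,0.2668
13,C,G,0.2224
13,C,T,0.3336
13,G,A,0.4003
13,G,C,0.2446
13,G,T,0.3558
13,T,A,0.2891
13,T,C,0.378
13,T,G,0.4225
14,A,C,0.2818
14,A,G,0.3422
14,A,T,0.2214
14,C,A,0.2416
14,C,G,0.2013
14,C,T,0.302
14,G,A,0.3624
14,G,C,0.2214
14,G,T,0.3221
14,T,A,0.2617
14,T,C,0.3422
14,T,G,0.3825
15,A,C,0.2524
15,A,G,0.3064
15,A,T,0.1983
15,C,A,0.2163
15,C,G,0.1803
15,C,T,0.2704
15,G,A,0.3245
15,G,C,0.1983
15,G,T,0.2884
15,T,A,0.2343
15,T,C,0.3064
15,T,G,0.3425
16,A,C,0.2229
16,A,G,0.2707
16,A,T,0.1751
16,C,A,0.1911
16,C,G,0.1592
16,C,T,0.2388
16,G,A,0.2866
16,G,C,0.1751
16,G,T,0.2547
16,T,A,0.207
16,T,C,0.2707
16,T,G,0.3025
17,A,C,0.1934
17,A,G,0.2349
17,A,T,0.152
17,C,A,0.1658
17,C,G,0.1382
17,C,T,0.2072
17,G,A,0.2487
17,G,C,0.152
17,G,T,0.2211
17,T,A,0.1796
17,T,C,0.2349
17,T,G,0.2625
18,A,C,0.1639
18,A,G,0.1991
18,A,T,0.1288
18,C,A,0.1405
18,C,G,0.1171
18,C,T,0.1757
18,G,A,0.2108
18,G,C,0.1288
18,G,T,0.1874
18,T,A,0.1522
18,T,C,0.1991
18,T,G,0.2225
19,A,C,0.1345
19,A,G,0.1633
19,A,T,0.1057
19,C,A,0.1153
19,C,G,0.0961
19,C,T,0.1441
19,G,A,0.1729
19,G,C,0.1057
19,G,T,0.1537
19,T,A,0.1249
19,T,C,0.1633
19,T,G,0.1825
20,A,C,0.105
20,A,G,0.1275
20,A,T,0.0825
20,C,A,0.09
20,C,G,0.075
20,C,T,0.1125
20,G,A,0.135
20,G,C,0.0825
20,G,T,0.12
20,T,A,0.0975
20,T,C,0.1275
20,T,G,0.1425
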