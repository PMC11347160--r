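# SYNTHETIC model CFD mismatch factors for enAsCas12a; not measured data.
# position 1 = PAM-distal end of the 20-nt spacer; guide_base = spacer base,
# site_base = protospacer-strand base observed at the (off-)target site.
position,guide_base,site_base,factor
1,A,C,0.644
1,A,G,0.782
1,A,T,0.506
1,C,A,0.552
1,C,G,0.46
1,C,T,0.69
1,G,A,0.828
1,G,C,0.506
1,G,T,0.736
1,T,A,0.598
1,T,C,0.782
1,T,G,0.874
2,A,C,0.6145
2,A,G,0.7462
2,A,T,0.4828
2,C,A,0.5267
2,C,G,0.4389
2,C,T,0.6584
2,G,A,0.7901
2,G,C,0.4828
2,G,T,0.7023
2,T,A,0.5706
2,T,C,0.7462
2,T,G,0.834
3,A,C,0.5851
3,A,G,0.7104
3,A,T,0.4597
3,C,A,0.5015
3,C,G,0.4179
3,C,T,0.6268
3,G,A,0.7522
3,G,C,0.4597
3,G,T,0.6686
3,T,A,0.5433
3,T,C,0.7104
3,T,G,0.794
4,A,C,0.5556
4,A,G,0.6746
4,A,T,0.4365
4,C,A,0.4762
4,C,G,0.3968
4,C,T,0.5953
4,G,A,0.7143
4,G,C,0.4365
4,G,T,0.6349
4,T,A,0.5159
4,T,C,0.6746
4,T,G,0.754
5,A,C,0.5261
5,A,G,0.6388
5,A,T,0.4134
5,C,A,0.4509
5,C,G,0.3758
5,C,T,0.5637
5,G,A,0.6764
5,G,C,0.4134
5,G,T,0.6013
5,T,A,0.4885
5,T,C,0.6388
5,T,G,0.714
6,A,C,0.4966
6,A,G,0.6031
6,A,T,0.3902
6,C,A,0.4257
6,C,G,0.3547
6,C,T,0.5321
6,G,A,0.6385
6,G,C,0.3902
6,G,T,0.5676
6,T,A,0.4612
6,T,C,0.6031
6,T,G,0.674
7,A,C,0.4672
7,A,G,0.5673
7,A,T,0.3671
7,C,A,0.4004
7,C,G,0.3337
7,C,T,0.5005
7,G,A,0.6006
7,G,C,0.3671
7,G,T,0.5339
7,T,A,0.4338
7,T,C,0.5673
7,T,G,0.634
8,A,C,0.4377
8,A,G,0.5315
8,A,T,0.3439
8,C,A,0.3752
8,C,G,0.3126
8,C,T,0.4689
8,G,A,0.5627
8,G,C,0.3439
8,G,T,0.5002
8,T,A,0.4064
8,T,C,0.5315
8,T,G,0.594
9,A,C,0.4082
9,A,G,0.4957
9,A,T,0.3207
9,C,A,0.3499
9,C,G,0.2916
9,C,T,0.4374
9,G,A,0.5248
9,G,C,0.3207
9,G,T,0.4665
9,T,A,0.3791
9,T,C,0.4957
9,T,G,0.554
10,A,C,0.3787
10,A,G,0.4599
10,A,T,0.2976
10,C,A,0.3246
10,C,G,0.2705
10,C,T,0.4058
10,G,A,0.4869
10,G,C,0.2976
10,G,T,0.4328
10,T,A,0.3517
10,T,C,0.4599
10,T,G,0.514
11,A,C,0.3493
11,A,G,0.4241
11,A,T,0.2744
11,C,A,0.2994
11,C,G,0.2495
11,C,T,0.3742
11,G,A,0.4491
11,G,C,0.2744
11,G,T,0.3992
11,T,A,0.3243
11,T,C,0.4241
11,T,G,0.474
12,A,C,0.3198
12,A,G,0.3883
12,A,T,0.2513
12,C,A,0.2741
12,C,G,0.2284
12,C,T,0.3426
12,G,A,0.4112
12,G,C,0.2513
12,G,T,0.3655
12,T,A,0.2969
12,T,C,0.3883
12,T,G,0.434
13,A,C,0.2903
13,A,G,0.3525
13,A,T,0.2281
13,C,A,0.2488
13,C,G,0.2074
13,C,T,0.3111
13,G,A,0.3733
13,G,C,0.2281
13,G,T,0.3318
13,T,A,0.2696
13,T,C,0.3525
13,T,G,0.394
14,A,C,0.2608
14,A,G,0.3167
14,A,T,0.2049
14,C,A,0.2236
14,C,G,0.1863
14,C,T,0.2795
14,G,A,0.3354
14,G,C,0.2049
14,G,T,0.2981
14,T,A,0.2422
14,T,C,0.3167
14,T,G,0.354
15,A,C,0.2314
15,A,G,0.2809
15,A,T,0.1818
15,C,A,0.1983
15,C,G,0.1653
15,C,T,0.2479
15,G,A,0.2975
15,G,C,0.1818
15,G,T,0.2644
15,T,A,0.2148
15,T,C,0.2809
15,T,G,0.314
16,A,C,0.2019
16,A,G,0.2452
16,A,T,0.1586
16,C,A,0.1731
16,C,G,0.1442
16,C,T,0.2163
16,G,A,0.2596
16,G,C,0.1586
16,G,T,0.2307
16,T,A,0.1875
16,T,C,0.2452
16,T,G,0.274
17,A,C,0.1724
17,A,G,0.2094
17,A,T,0.1355
17,C,A,0.1478
17,C,G,0.1232
17,C,T,0.1847
17,G,A,0.2217
17,G,C,0.1355
17,G,T,0.1971
17,T,A,0.1601
17,T,C,0.2094
17,T,G,0.234
18,A,C,0.1429
18,A,G,0.1736
18,A,T,0.1123
18,C,A,0.1225
18,C,G,0.1021
18,C,T,0.1532
18,G,A,0.1838
18,G,C,0.1123
18,G,T,0.1634
18,T,A,0.1327
18,T,C,0.1736
18,T,G,0.194
19,A,C,0.1135
19,A,G,0.1378
19,A,T,0.0892
19,C,A,0.0973
19,C,G,0.0811
19,C,T,0.1216
19,G,A,0.1459
19,G,C,0.0892
19,G,T,0.1297
19,T,A,0.1054
19,T,C,0.1378
19,T,G,0.154
20,A,C,0.084
20,A,G,0.102
20,A,T,0.066
20,C,A,0.072
20,C,G,0.06
20,C,T,0.09
20,G,A,0.108
20,G,C,0.066
20,G,T,0.096
20,T,A,0.078
20,T,C,0.102
20,T,G,0.114
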