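# structure: PTV_upperOverlap
# arc_set: US
# dose_units: absolute_gy
# prescription_gy: 36.0000
dose	volume_pct
0.0000	99.3245
0.2500	99.2763
0.5000	99.2248
0.7500	99.1696
1.0000	99.1106
1.2500	99.0473
1.5000	98.9797
1.7500	98.9072
2.0000	98.8297
2.2500	98.7468
2.5000	98.6580
2.7500	98.5631
3.0000	98.4615
3.2500	98.3529
3.5000	98.2368
3.7500	98.1126
4.0000	97.9799
4.2500	97.8381
4.5000	97.6865
4.7500	97.5245
5.0000	97.3516
5.2500	97.1669
5.5000	96.9697
5.7500	96.7593
6.0000	96.5347
6.2500	96.2952
6.5000	96.0398
6.7500	95.7676
7.0000	95.4776
7.2500	95.1687
7.5000	94.8398
7.7500	94.4899
8.0000	94.1176
8.2500	93.7220
8.5000	93.3015
8.7500	92.8551
9.0000	92.3814
9.2500	91.8790
9.5000	91.3465
9.7500	90.7827
10.0000	90.1861
10.2500	89.5552
10.5000	88.8889
10.7500	88.1856
11.0000	87.4441
11.2500	86.6631
11.5000	85.8414
11.7500	84.9779
12.0000	84.0714
12.2500	83.1212
12.5000	82.1262
12.7500	81.0860
13.0000	80.0000
13.2500	78.8679
13.5000	77.6895
13.7500	76.4651
14.0000	75.1949
14.2500	73.8796
14.5000	72.5200
14.7500	71.1174
15.0000	69.6730
15.2500	68.1888
15.5000	66.6667
15.7500	65.1090
16.0000	63.5183
16.2500	61.8976
16.5000	60.2499
16.7500	58.5786
17.0000	56.8874
17.2500	55.1800
17.5000	53.4602
17.7500	51.7322
18.0000	50.0000
18.2500	48.2678
18.5000	46.5398
18.7500	44.8200
19.0000	43.1126
19.2500	41.4214
19.5000	39.7501
19.7500	38.1024
20.0000	36.4817
20.2500	34.8910
20.5000	33.3333
20.7500	31.8112
21.0000	30.3270
21.2500	28.8826
21.5000	27.4800
21.7500	26.1204
22.0000	24.8051
22.2500	23.5349
22.5000	22.3105
22.7500	21.1321
23.0000	20.0000
23.2500	18.9140
23.5000	17.8738
23.7500	16.8788
24.0000	15.9286
24.2500	15.0221
24.5000	14.1586
24.7500	13.3369
25.0000	12.5559
25.2500	11.8144
25.5000	11.1111
25.7500	10.4448
26.0000	9.8139
26.2500	9.2173
26.5000	8.6535
26.7500	8.1210
27.0000	7.6186
27.2500	7.1449
27.5000	6.6985
27.7500	6.2780
28.0000	5.8824
28.2500	5.5101
28.5000	5.1602
28.7500	4.8313
29.0000	4.5224
29.2500	4.2324
29.5000	3.9602
29.7500	3.7048
30.0000	3.4653
30.2500	3.2407
30.5000	3.0303
30.7500	2.8331
31.0000	2.6484
31.2500	2.4755
31.5000	2.3135
31.7500	2.1619
32.0000	2.0201
32.2500	1.8874
32.5000	1.7632
32.7500	1.6471
33.0000	1.5385
33.2500	1.4369
33.5000	1.3420
33.7500	1.2532
34.0000	1.1703
34.2500	1.0928
34.5000	1.0203
34.7500	0.9527
35.0000	0.8894
35.2500	0.8304
35.5000	0.7752
35.7500	0.7237
36.0000	0.6755
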