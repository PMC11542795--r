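# structure: PTV_upperOverlap
# arc_set: UD
# dose_units: absolute_gy
# prescription_gy: 36.0000
dose	volume_pct
0.0000	100.0000
0.2500	99.3056
0.5000	98.6111
0.7500	97.9167
1.0000	97.2222
1.2500	96.5278
1.5000	95.8333
1.7500	95.1389
2.0000	94.4444
2.2500	93.7500
2.5000	93.0556
2.7500	92.3611
3.0000	91.6667
3.2500	90.9722
3.5000	90.2778
3.7500	89.5833
4.0000	88.8889
4.2500	88.1944
4.5000	87.5000
4.7500	86.8056
5.0000	86.1111
5.2500	85.4167
5.5000	84.7222
5.7500	84.0278
6.0000	83.3333
6.2500	82.6389
6.5000	81.9444
6.7500	81.2500
7.0000	80.5556
7.2500	79.8611
7.5000	79.1667
7.7500	78.4722
8.0000	77.7778
8.2500	77.0833
8.5000	76.3889
8.7500	75.6944
9.0000	75.0000
9.2500	74.3056
9.5000	73.6111
9.7500	72.9167
10.0000	72.2222
10.2500	71.5278
10.5000	70.8333
10.7500	70.1389
11.0000	69.4444
11.2500	68.7500
11.5000	68.0556
11.7500	67.3611
12.0000	66.6667
12.2500	65.9722
12.5000	65.2778
12.7500	64.5833
13.0000	63.8889
13.2500	63.1944
13.5000	62.5000
13.7500	61.8056
14.0000	61.1111
14.2500	60.4167
14.5000	59.7222
14.7500	59.0278
15.0000	58.3333
15.2500	57.6389
15.5000	56.9444
15.7500	56.2500
16.0000	55.5556
16.2500	54.8611
16.5000	54.1667
16.7500	53.4722
17.0000	52.7778
17.2500	52.0833
17.5000	51.3889
17.7500	50.6944
18.0000	50.0000
18.2500	49.3056
18.5000	48.6111
18.7500	47.9167
19.0000	47.2222
19.2500	46.5278
19.5000	45.8333
19.7500	45.1389
20.0000	44.4444
20.2500	43.7500
20.5000	43.0556
20.7500	42.3611
21.0000	41.6667
21.2500	40.9722
21.5000	40.2778
21.7500	39.5833
22.0000	38.8889
22.2500	38.1944
22.5000	37.5000
22.7500	36.8056
23.0000	36.1111
23.2500	35.4167
23.5000	34.7222
23.7500	34.0278
24.0000	33.3333
24.2500	32.6389
24.5000	31.9444
24.7500	31.2500
25.0000	30.5556
25.2500	29.8611
25.5000	29.1667
25.7500	28.4722
26.0000	27.7778
26.2500	27.0833
26.5000	26.3889
26.7500	25.6944
27.0000	25.0000
27.2500	24.3056
27.5000	23.6111
27.7500	22.9167
28.0000	22.2222
28.2500	21.5278
28.5000	20.8333
28.7500	20.1389
29.0000	19.4444
29.2500	18.7500
29.5000	18.0556
29.7500	17.3611
30.0000	16.6667
30.2500	15.9722
30.5000	15.2778
30.7500	14.5833
31.0000	13.8889
31.2500	13.1944
31.5000	12.5000
31.7500	11.8056
32.0000	11.1111
32.2500	10.4167
32.5000	9.7222
32.7500	9.0278
33.0000	8.3333
33.2500	7.6389
33.5000	6.9444
33.7500	6.2500
34.0000	5.5556
34.2500	4.8611
34.5000	4.1667
34.7500	3.4722
35.0000	2.7778
35.2500	2.0833
35.5000	1.3889
35.7500	0.6944
36.0000	0.0000
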