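cluster,y,event,arm
1,3.41797,1,0
1,1.15527,1,0
1,1.02287,1,1
1,0.570014,1,1
1,1.89099,1,0
1,2.93001,1,1
1,1.39113,1,0
1,0.0078925,1,1
2,5.24494,1,1
2,0.207069,1,0
2,2.83069,1,1
2,1.15119,1,1
2,19.6778,1,0
2,7.01762,1,0
2,3.57895,1,0
3,4.18076,1,1
3,11.1617,1,1
3,31.0343,0,0
3,31.0343,0,0
3,31.0343,0,0
4,31.0343,0,0
4,31.0343,0,1
5,25.5837,1,0
5,3.92656,1,1
5,6.73935,1,1
5,29.6125,1,0
5,26.5126,1,0
5,12.5345,1,1
5,12.8028,1,1
5,6.18177,1,0
6,31.0343,0,0
6,31.0343,0,0
6,31.0343,0,1
6,31.0343,0,1
7,10.1602,1,0
7,0.922604,1,1
7,31.0343,0,0
7,14.5243,1,1
8,31.0343,0,0
8,31.0343,0,1
8,31.0343,0,0
8,19.9704,1,1
8,31.0343,0,0
9,1.46957,1,0
9,0.30366,1,0
9,1.08165,1,1
9,8.40956,1,1
10,0.255153,1,1
10,0.540036,1,1
10,1.70784,1,1
10,5.9151,1,0
10,2.40434,1,1
10,3.47074,1,0
10,2.17551,1,0
10,20.4971,1,0
11,31.0343,0,0
11,31.0343,0,0
11,31.0343,0,1
11,31.0343,0,0
11,31.0343,0,1
11,31.0343,0,0
11,31.0343,0,0
11,31.0343,0,1
11,30.8774,1,1
12,2.22849,1,1
12,2.59093,1,0
13,1.45843,1,1
13,3.07415,1,0
13,24.364,1,0
13,30.3446,1,1
13,13.2076,1,0
14,23.5555,1,0
14,31.0343,0,0
14,23.0877,1,1
15,2.7596,1,1
15,17.0122,1,0
15,3.5842,1,1
15,8.12355,1,1
15,1.10205,1,1
15,31.0343,0,0
15,6.48877,1,0
15,22.203,1,0
16,0.0670105,1,1
16,15.7616,1,0
16,4.96621,1,0
17,4.36439,1,0
17,31.0343,0,0
17,21.5182,1,0
17,11.3398,1,1
17,1.75712,1,1
17,13.4262,1,1
17,27.5652,1,0
17,23.4129,1,1
18,31.0343,0,1
18,24.5369,1,0
18,31.0343,0,0
18,31.0343,0,0
18,3.96117,1,1
18,30.559,1,0
18,31.0343,0,1
19,5.13243,1,0
19,4.20207,1,0
19,6.24173,1,1
19,13.7496,1,1
19,18.6264,1,0
19,2.05847,1,1
20,7.78581,1,0
20,15.226,1,1
20,1.99481,1,1
20,12.0875,1,0
21,31.0343,0,1
21,31.0343,0,0
21,31.0343,0,0
21,31.0343,0,1
21,31.0343,0,0
21,23.9822,1,1
21,31.0343,0,0
22,31.0343,0,0
22,31.0343,0,0
22,31.0343,0,0
22,4.3179,1,1
22,31.0343,0,0
22,31.0343,0,0
22,31.0343,0,1
22,9.41548,1,1
22,2.17823,1,1
23,3.62602,1,1
23,4.83086,1,1
23,1.61765,1,0
23,11.6898,1,0
23,1.29352,1,0
24,5.20991,1,0
24,2.22839,1,0
24,5.14569,1,0
24,1.41965,1,1
24,2.11138,1,1
24,0.879718,1,1
25,6.5039,1,0
25,0.0248301,1,1
26,2.01639,1,1
26,3.75353,1,0
27,7.42912,1,0
27,1.30824,1,1
27,3.92443,1,1
27,1.73608,1,1
27,11.9202,1,0
27,7.09242,1,0
27,0.251087,1,0
28,31.0343,0,0
28,5.26541,1,1
28,4.48669,1,0
28,23.72,1,1
29,31.0343,0,0
29,31.0343,0,1
29,24.8741,1,1
29,31.0343,0,0
30,8.9616,1,0
30,2.35007,1,1
30,0.613616,1,0
30,4.43996,1,0
30,0.932263,1,1
31,5.02149,1,1
31,2.1398,1,0
31,0.531472,1,0
31,0.0605942,1,1
32,2.85085,1,1
32,15.7588,1,0
32,8.95791,1,1
32,9.76874,1,0
32,5.51921,1,0
32,5.15015,1,1
32,0.0942539,1,1
32,2.22446,1,0
33,9.21265,1,1
33,1.73467,1,0
34,2.41421,1,0
34,0.954364,1,1
34,0.415926,1,0
34,12.5682,1,1
35,21.7016,1,0
35,10.912,1,0
35,8.15309,1,1
36,28.4743,1,1
36,4.61256,1,0
37,27.349,1,0
37,10.9938,1,0
37,16.5391,1,1
37,0.67929,1,1
37,7.77991,1,0
37,6.12913,1,1
37,4.39595,1,0
38,1.7232,1,0
38,14.0031,1,1
38,9.62367,1,0
38,15.0314,1,1
38,18.1906,1,0
38,3.58045,1,1
39,31.0343,0,0
39,6.51432,1,1
39,0.230087,1,0
39,31.0343,0,0
39,16.947,1,1
40,11.1743,1,0
40,0.708443,1,0
40,0.364334,1,0
40,0.531537,1,0
40,16.927,1,1
40,1.4263,1,1
40,4.88125,1,1
40,3.11783,1,1
40,1.05743,1,0
41,4.77223,1,0
41,1.25487,1,0
41,8.43211,1,1
41,9.01257,1,1
41,8.92921,1,1
41,1.58239,1,0
41,11.5233,1,0
42,31.0343,0,0
42,27.7122,1,0
42,0.532261,1,1
42,27.5716,1,1
42,6.05335,1,0
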