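# p: 6
# n_sims: 50000
# seed: 20220627
r	kappa
0.5	0
0.75	0
1	0
1.25	0
1.5	0
1.75	0
2	0
2.25	0
2.5	0
2.75	0
3	0
3.25	0
3.5	0
3.75	0
4	0.03487026393
4.25	0.1695338444
4.5	0.3724504338
4.75	0.5293435493
5	0.6754185676
5.25	0.8050916523
5.5	0.9377085614
5.75	1.086368923
6	1.197664868
6.25	1.347272944
6.5	1.43518953
6.75	1.560948676
7	1.658486021
7.25	1.775245278
7.5	1.900633185
7.75	2.016139717
8	2.137037365
8.25	2.217127478
8.5	2.346001116
8.75	2.467108031
9	2.60038695
9.25	2.726513133
9.5	2.819525979
9.75	2.969805272
10	3.097435489
10.25	3.180790557
10.5	3.368440044
10.75	3.517653657
11	3.658684417
11.25	3.832912134
11.5	3.941464006
11.75	4.098322899
12	4.292319243
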