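# p: 2
# n_sims: 50000
# seed: 20220627
r	kappa
0.5	0.002076325881
0.75	0
1	0.01370759414
1.25	0.02462743899
1.5	0.03010749009
1.75	0.08099926778
2	0.1705754635
2.25	0.315962925
2.5	0.4899549062
2.75	0.6659816665
3	0.800981395
3.25	0.9582289552
3.5	1.158199517
3.75	1.282815652
4	1.42382109
4.25	1.614519174
4.5	1.780026667
4.75	1.990022505
5	2.150366987
5.25	2.292424206
5.5	2.446061976
5.75	2.600881381
6	2.82928282
6.25	3.017700931
6.5	3.187581339
6.75	3.346939163
7	3.625791813
7.25	3.810892754
7.5	4.108465267
7.75	4.258986485
8	4.440001721
8.25	4.794167157
8.5	4.994738051
8.75	5.212471839
9	5.774294007
9.25	5.96585929
9.5	6.206994972
9.75	6.341396151
10	6.866973435
10.25	6.98927482
10.5	7.434020368
10.75	7.71608423
11	7.854279654
11.25	8.188380649
11.5	8.734235723
11.75	9.013510556
12	9.530999105
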