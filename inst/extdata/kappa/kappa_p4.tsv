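# p: 4
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
3.25	0.03174039082
3.5	0.2138015791
3.75	0.393045822
4	0.5657470935
4.25	0.7561796067
4.5	0.8746321024
4.75	1.053271527
5	1.150088972
5.25	1.33163658
5.5	1.433140774
5.75	1.596473386
6	1.745144876
6.25	1.871843489
6.5	1.991440898
6.75	2.147362954
7	2.247299888
7.25	2.389447405
7.5	2.572650095
7.75	2.672319322
8	2.805298847
8.25	2.954973382
8.5	3.104320083
8.75	3.287575628
9	3.481997754
9.25	3.660344459
9.5	3.712123375
9.75	3.987105693
10	4.126350166
10.25	4.338035106
10.5	4.506675933
10.75	4.606531372
11	4.980497553
11.25	5.110080851
11.5	5.268287383
11.75	5.527968446
12	5.739873176
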