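# p: 3
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
2.75	0.1055938574
3	0.2515153216
3.25	0.4753386585
3.5	0.6007938462
3.75	0.7980976833
4	0.9048317603
4.25	1.085057769
4.5	1.20221323
4.75	1.36928899
5	1.562789215
5.25	1.699563412
5.5	1.868482942
5.75	1.999439707
6	2.152408396
6.25	2.287527866
6.5	2.454128735
6.75	2.617000973
7	2.695643199
7.25	2.950154143
7.5	3.066595609
7.75	3.238576458
8	3.347604275
8.25	3.65880778
8.5	3.856901339
8.75	3.984272602
9	4.145224896
9.25	4.313735517
9.5	4.599177189
9.75	4.882040984
10	4.885115996
10.25	5.218155611
10.5	5.474755534
10.75	5.741928863
11	6.040952395
11.25	6.162010248
11.5	6.630097877
11.75	6.692927335
12	6.937523679
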