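# p: 5
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
3.75	0.09878023323
4	0.2949578155
4.25	0.4426548298
4.5	0.607550586
4.75	0.7699333108
5	0.9059420554
5.25	1.018410474
5.5	1.20670801
5.75	1.308149419
6	1.445999582
6.25	1.571927924
6.5	1.666126419
6.75	1.809843725
7	1.927394867
7.25	2.060250052
7.5	2.176315674
7.75	2.296358548
8	2.410814228
8.25	2.571850122
8.5	2.719142926
8.75	2.831959358
9	2.962745425
9.25	3.111523811
9.5	3.212317777
9.75	3.371229035
10	3.521934144
10.25	3.627594951
10.5	3.836331772
10.75	4.000474655
11	4.068718435
11.25	4.368140318
11.5	4.524586126
11.75	4.659173146
12	4.861644327
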