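chrom	snp	pos_mb	alpha	q_value	n_outliers_chrom	colocal_dairy_scan	colocal_worldwide_scan
1	s28145.1	256.60	1.32	0.033	3
1	OAR1_77069506.1	72.00	1.28	0.038	3
1	s61441.1	27.80	1.24	0.043	3
2	OAR2_194667510.1	183.60	1.49	0.006	8
2	s38806.1	247.00	1.73	0.010	8
2	OAR2_25448426.1	25.00	1.44	0.017	8
2	OAR2_150515619.1	141.50	1.36	0.020	8
2	s58048.1	52.40	1.39	0.021	8	52.3-52.5	51.4-53.4
2	s17630.1	6.70	1.31	0.028	8
2	OAR2_56768579.1	52.90	1.29	0.031	8	52.3-52.5	51.4-53.4
2	OAR2_83850165.1	78.60	1.29	0.036	8
3	OAR3_203907310.1	189.30	1.47	0.007	5
3	s29466.1	18.40	1.52	0.005	5	18.9-19.3
3	OAR3_164170826.1	153.50	1.36	0.023	5	153.4-154.5	151.4-156.9
3	s38388.1	201.40	1.30	0.034	5
3	s19983.1	93.80	1.26	0.041	5
6	OAR6_44123475_X.1	39.40	1.28	0.040	1	39.3-39.5	35.9-38.3
7	OAR7_30772408.1	27.00	1.40	0.018	4
7	s68972.1	43.70	1.63	0.001	4
7	s11241.1	27.00	1.45	0.011	4
7	OAR7_1827930.1	2.10	1.28	0.047	4
9	OAR9_14653377.1	14.30	1.40	0.014	1
10	OAR10_90168545.1	82.50	1.81	0.003	3
10	OAR10_23129120.1	23.50	1.43	0.012	3		24.02-34.91
10	OAR10_79676247.1	72.70	1.35	0.025	3
12	s34065.1	37.90	1.25	0.045	1
13	s56762.1	2.00	1.52	0.004	4
13	s38696.1	74.30	1.50	0.008	4
13	s05603.1	72.00	1.37	0.015	4
13	s19740.1	22.90	1.27	0.050	4
14	OAR14_9498278.1	9.10	2.04	0.000	1		6.3-13.6
15	s45350.1	20.60	1.23	0.048	1	16.6-20.6
17	OAR17_33487124.1	30.60	1.44	0.010	2
17	OAR17_23200636.1	20.70	1.47	0.009	2
19	s18836.1	51.30	1.37	0.026	2
19	OAR19_33355170.1	31.60	1.50	0.006	2		30.4-35.09
24	s06827.1	13.10	1.46	0.008	1
25	s67158.1	7.70	1.43	0.013	2
25	OAR25_23589759.1	22.60	1.31	0.029	2
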