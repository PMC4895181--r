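chrom	start_mb	end_mb	snp_left	snp_right	n_snps	raw_p	q_value	colocal_dairy_scan	colocal_worldwide_scan	bayescan_confirmed
2	82.8	87.7	OAR2_88062818.1	s35257.1	97	0.034	0.574	83.1-85.3	81.2-87.3	FALSE
3	150.5	154.2	s26286.1	OAR3_165050963.1	68	0.029	0.545	153.4-154.5	151.4-156.9	TRUE
5	46.5	49.1	s59995.1	OAR5_53435489.1	48	0.007	0.213		47.3-49.3	FALSE
6	4.3	49.9	OAR6_6402059.1	OAR6_55087517_X.1	860	0.000	0.000	39.3-39.5	35.9-38.3	TRUE
6	52.3	52.6	OAR6_57796972.1	OAR6_58069886.1	7	0.049	0.604			FALSE
6	64.5	74.3	OAR6_70844973.1	OAR6_81183719.1	180	0.016	0.389	69.9-70.5	67.9-70.3	FALSE
6	112.1	115.6	OAR6_127397796.1	s33220.1	58	0.026	0.52			FALSE
10	29.1	29.3	OAR10_29159858.1	OAR10_29381795.1	7	0.044	0.598		29.4-29.7	FALSE
13	43.6	50.9	s39429.1	OAR13_55448085.1	104	0.006	0.192	48.9-52.0	43.3-51.2	FALSE
13	68.8	74.9	OAR13_74074760.1	OAR13_80614774_X.1	97	0.025	0.524			TRUE
16	24.7	25.2	s59907.1	OAR16_27501072.1	13	0.043	0.598			FALSE
17	61.2	67.1	s25636.1	s73670.1	34	0.039	0.591			FALSE
24	6.9	11.0	OAR24_8063846.1	s18520.1	44	0.042	0.598			FALSE
25	24.8	45.3	OAR25_25923466.1	OAR25_48288071_X.1	353	0.008	0.249			FALSE
26	0.16	3.8	OAR26_222715_X.1	s54858.1	47	0.030	0.547			FALSE
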