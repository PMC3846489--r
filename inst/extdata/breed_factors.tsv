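breed	type	train_size	validation_size	error_rate_pct	ld70	r_tv	n_eff_ancestors
Abondance	dairy	169	40	0.75	0.217	0.146	15
Brown Swiss	dairy	79	20	1.92	0.255	0.074	28
Holstein	dairy	634	154	0.73	0.255	0.078	21
Montbeliarde	dairy	424	106	0.51	0.196	0.116	18
Normande	dairy	444	107	0.33	0.233	0.104	23
Simmental	dairy	100	25	2.55	0.209	0.050	39
Aubrac	beef	204	50	2.03	0.177	0.028	112
Bazadaise	beef	72	17	2.07	0.239	0.038	46
Blonde d'Aquitaine	beef	262	65	1.80	0.175	0.038	78
Charolais	beef	539	133	0.68	0.176	0.018	249
Gasconne	beef	131	32	2.26	0.174	0.026	197
Limousine	beef	370	92	1.09	0.164	0.014	185
Parthenaise	beef	245	59	1.88	0.161	0.024	89
Rouge des Pres	beef	119	30	2.39	0.206	0.028	99
Salers	beef	197	49	1.27	0.213	0.024	99
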