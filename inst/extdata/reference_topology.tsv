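cultivar	stage	connected_nodes	isolated_nodes	edges	connected_components	diameter	average_path_length	density	cluster_coefficient
CS	FLW	70	45	154	9	9	3.341	0.023	0.252
CS	FS	94	21	625	3	7	2.463	0.095	0.424
CS	PRV	66	49	86	9	9	3.889	0.013	0.158
CS	VR	55	60	66	11	6	2.637	0.010	0.122
CS	PSV	67	48	72	15	9	2.660	0.011	0.142
CS	RP	62	53	67	17	5	1.725	0.010	0.133
ME	FLW	79	36	183	7	8	3.489	0.028	0.270
ME	FS	89	26	455	3	8	2.945	0.069	0.366
ME	PRV	59	56	61	15	6	2.802	0.009	0.149
ME	VR	76	39	276	5	9	3.417	0.042	0.285
ME	PSV	62	53	86	13	7	3.129	0.013	0.145
ME	RP	59	56	52	15	6	2.294	0.008	0.093
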