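qtl	trait	chrom	pos	left_marker	right_marker	lod	pve	add	ci_left	ci_right	environment
QRL_C4A	RL	4A	101.00	Kukri_c48943_1149	Excalibur_c3988_1660	2.73	16.70	-1.82	89.50	113.50	Control
QFW_D3A	FW	3A	33.00	Tdurum_contig52302_649	BobWhite_c37325_92	2.74	14.43	-0.10	31.50	33.50	Drought
QFW_D3B	FW	3B	102.00	IAAV6566	Tdurum_contig100004_204	3.43	18.59	-0.12	90.50	106.50	Drought
QSL_D2A	SL	2A	85.00	RAC875_c4015_2175	BobWhite_c1611_1685	2.85	21.72	0.74	83.50	92.50	Drought
QFG_D7B	FG	7B	181.00	RAC875_rep_c108382_824	BS00063821_51	2.54	17.22	5.62	179.50	181.50	Drought
QCVt_D3B	CVt	3B	97.00	RAC875_c81076_317	IAAV6566	2.50	16.43	7.30	87.50	106.50	Drought
QFW_CN3B	FW	3B	83.00	RAC875_c5799_224	RAC875_c81076_317	2.76	19.36	-0.16	62.50	98.50	Control and Nano
QFW_DN3B	FW	3B	102.00	IAAV6566	Tdurum_contig100004_204	2.60	17.59	-0.11	89.50	106.50	Drought and Nano
QSL_DN1A	SL	1A	13.00	wsnp_Ex_c7965_13520238	wsnp_Ku_c5756_10191339	2.51	17.00	-0.79	11.50	16.50	Drought and Nano
QRNo_DN1A	RNo	1A	111.00	BobWhite_c12977_65	BS00039378_51	2.79	18.45	-0.32	102.50	110.50	Drought and Nano
QCVt_DN2B	CVt	2B	168.00	RAC875_c27650_216	Excalibur_c7051_1027	14.07	3.45	17.83	166.50	168.50	Drought and Nano
QFG_DN7B	FG	7B	175.00	CAP12_c194_240	Excalibur_c24639_398	2.07	14.19	6.08	161.50	179.50	Drought and Nano
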