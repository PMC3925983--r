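comparison	parent	child	kind	position	length
MZT1a_vs_MZT1b	MZT1a	MZT1b	deletion	390	20
MZT1a_vs_MZT1b	MZT1a	MZT1b	deletion	1728	15
MZT2b_vs_MZT2a	MZT2b	MZT2a	deletion	411	16
MZT2b_vs_MZT2a	MZT2b	MZT2a	deletion	765	15
MZT3a_vs_MZT3b	MZT3a	MZT3b	deletion	1068	1
MZT3a_vs_MZT3b	MZT3a	MZT3b	deletion	1580	5
MZT3a_vs_MZT3b	MZT3a	MZT3b	insertion	1668	1
MZT3a_vs_MZT3b	MZT3a	MZT3b	insertion	2515	15
MZT1a_blood_vs_MZT1a_germline	MZT1a_blood	MZT1a_germline	deletion	410	5
MZT1b_germline_vs_MZT1b_blood	MZT1b_germline	MZT1b_blood	deletion	390	15
MZT1b_germline_vs_MZT1b_blood	MZT1b_germline	MZT1b_blood	deletion	1722	15
MZT1b_germline_vs_MZT1b_blood	MZT1b_germline	MZT1b_blood	insertion	844	1
MZT1b_germline_vs_MZT1b_blood	MZT1b_germline	MZT1b_blood	insertion	3487	1
MZT1b_germline_vs_MZT1b_blood	MZT1b_germline	MZT1b_blood	insertion	3518	1
MZT1b_germline_vs_MZT1b_blood	MZT1b_germline	MZT1b_blood	insertion	3540	1
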