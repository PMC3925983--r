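row	MZT1a	MZT1b	MZT2a	MZT2b	MZT3a	MZT3b
TTCCA	235	226	221	228	184	190
1 bp derivatives	290	289	286	295	245	238
ATCCA	9	9	9	9	7	7
TACCA	3	3	3	3	2	2
TTACA	16	16	15	16	12	11
TTCAA	21	21	22	23	21	19
TTTCA	19	19	18	19	17	15
TTCTA	25	26	24	25	24	23
TTCCT	33	33	34	30	29	27
GTCCA	29	29	30	31	26	26
TGCCA	10	9	9	9	8	8
TTGCA	23	22	24	25	16	18
TTCGA	60	60	55	62	50	51
TTCCG	17	17	19	18	14	14
CTCCA	14	14	12	14	10	10
TCCCA	4	4	4	4	2	2
TTCCC	7	7	8	7	7	5
2 bp derivatives	142	140	154	139	116	120
3 bp derivatives	33	36	32	37	28	28
4 bp derivatives	9	11	9	8	9	8
5 bp derivatives	1	1	1	1	1	1
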