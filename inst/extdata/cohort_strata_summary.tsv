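sex	age_group	n	mean_age	sd_age	smoking	diabetes	hypertension	high_cholesterol	familial_cad	stemi	nstemi	uap	sap
male	very_young	10	36.9	2.7	7	0	0	2	5	8	1	0	1
male	young	297	49.8	3.6	176	28	102	114	144	179	33	14	71
male	intermediate	537	63.3	4.3	299	81	272	252	216	267	68	36	166
male	old	308	76.6	4.6	125	50	175	137	83	128	32	24	124
female	very_young	36	45.5	4.2	26	6	8	7	15	20	4	3	9
female	young	153	58.3	4.4	99	13	67	68	80	73	23	12	45
female	intermediate	188	72.7	3.9	80	37	125	109	93	62	36	16	74
female	old	70	85.1	3.8	26	9	49	24	25	39	8	2	21
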