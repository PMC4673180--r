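miRNA	HC	LTC	LTP	STC	STP
hsa-miR-1185-5p	59	16	8	10	10
hsa-miR-1224-3p	245	29	7	4	25
hsa-miR-124-5p	359	83	13	36	26
hsa-miR-1249	1468	153	199	64	275
hsa-miR-127-5p	104	23	7	23	11
hsa-miR-128-3p	28670	4382	2616	3413	6134
hsa-miR-129-1-3p	343	55	16	16	61
hsa-miR-129-2-3p	6142	1786	321	292	695
hsa-miR-129-5p	494	126	60	29	94
hsa-miR-137	446	98	18	41	100
hsa-miR-139-3p	74	20	0	0	6
hsa-miR-139-5p	20625	3441	1018	547	2306
hsa-miR-154-3p	216	43	35	63	71
hsa-miR-3200-3p	416	19	5	0	14
hsa-miR-323a-3p	2795	610	246	289	389
hsa-miR-323b-3p	330	68	24	34	63
hsa-miR-326	1204	423	216	103	183
hsa-miR-329-3p	1241	255	53	125	236
hsa-miR-369-3p	142	38	15	47	30
hsa-miR-376a-5p	100	32	6	19	16
hsa-miR-381-5p	89	27	3	8	11
hsa-miR-431-3p	81	16	0	3	4
hsa-miR-485-3p	387	90	16	41	38
hsa-miR-487a-3p	226	57	29	51	55
hsa-miR-487b-3p	5864	1661	414	412	773
hsa-miR-491-5p	166	54	8	4	12
hsa-miR-504-5p	460	107	58	9	16
hsa-miR-582-5p	331	46	54	85	75
hsa-miR-628-5p	504	163	152	44	132
hsa-miR-6511b-3p	190	50	46	25	47
hsa-miR-656-3p	123	23	11	14	26
hsa-miR-668-3p	57	12	3	4	5
hsa-miR-7-1-3p	521	150	148	146	179
hsa-miR-7-2-3p	143	19	10	12	22
hsa-miR-769-3p	271	42	26	23	27
hsa-miR-769-5p	355	60	19	79	104
hsa-miR-770-5p	190	55	4	8	12
hsa-miR-874-3p	3834	1002	590	470	748
hsa-miR-99b-5p	1186	71	217	121	171
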