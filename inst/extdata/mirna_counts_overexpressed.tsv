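miRNA	HC	LTC	LTP	STC	STP
hsa-miR-106b-5p	119	537	1025	2887	1222
hsa-miR-10b-5p	11	557	1445	1589	311
hsa-miR-1248	18	255	128	174	101
hsa-miR-1260a	151	1033	906	933	431
hsa-miR-1260b	14	101	128	66	82
hsa-miR-148a-3p	89	529	266	588	300
hsa-miR-16-2-3p	15	51	72	156	50
hsa-miR-182-5p	11	75	52	1322	230
hsa-miR-183-5p	2	51	15	508	87
hsa-miR-18a-5p	35	135	441	460	329
hsa-miR-210-3p	3	214	212	355	199
hsa-miR-21-3p	0	37	37	68	10
hsa-miR-21-5p	1132	15222	40876	51388	7627
hsa-miR-24-2-5p	6	59	76	70	36
hsa-miR-3065-5p	7	134	47	36	32
hsa-miR-454-3p	33	208	173	344	319
hsa-miR-503-5p	5	23	22	74	17
hsa-miR-92b-5p	2	33	108	74	18
hsa-miR-93-5p	1439	6443	7835	12378	6080
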