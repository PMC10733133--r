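group	pool	total	normal	died	abnormal_morphology	abnormal_behavior
DV1_8	A	228	196	11	20	1
DV1_8	B	128	88	15	23	2
DV1_8	C	214	184	11	18	1
DV1_8	D	171	139	24	7	1
DV1_8	E	210	180	15	12	3
DV1_10	A	204	194	4	6	0
DV1_10	B	140	135	4	1	0
DV1_10	C	193	184	5	2	2
DV1_10	D	125	121	3	1	0
DV1_10	E	193	185	7	1	0
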