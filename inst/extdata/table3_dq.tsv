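DQA10101-DQB10501	153	161
DQA10101-DQB10501	154	162
DQA10101-DQB10501	159	167
DQA10101-DQB10501	160	168
DQA10102-DQB10602	33	41
DQA10102-DQB10602	40	48
DQA10102-DQB10602	42	50
DQA10102-DQB10602	57	65
DQA10102-DQB10602	77	85
DQA10102-DQB10602	117	125
DQA10102-DQB10602	154	162
DQA10102-DQB10602	192	200
DQA10102-DQB10602	206	214
DQA10102-DQB10602	213	221
DQA10102-DQB10602	230	238
DQA10102-DQB10602	237	245
DQA10501-DQB10201	19	27
DQA10501-DQB10201	39	47
DQA10501-DQB10201	37	45
DQA10501-DQB10201	82	90
DQA10501-DQB10201	100	108
DQA10501-DQB10201	112	120
DQA10501-DQB10201	122	130
DQA10501-DQB10201	126	134
DQA10501-DQB10201	158	166
DQA10501-DQB10201	195	203
DQA10501-DQB10201	220	228
DQA10501-DQB10301	6	14
DQA10501-DQB10301	34	42
DQA10501-DQB10301	38	46
DQA10501-DQB10301	39	47
DQA10501-DQB10301	58	66
DQA10501-DQB10301	66	74
DQA10501-DQB10301	69	77
DQA10501-DQB10301	72	80
DQA10501-DQB10301	74	82
DQA10501-DQB10301	77	85
DQA10501-DQB10301	82	90
DQA10501-DQB10301	85	93
DQA10501-DQB10301	107	115
DQA10501-DQB10301	117	125
DQA10501-DQB10301	121	129
DQA10501-DQB10301	133	141
DQA10501-DQB10301	161	169
DQA10501-DQB10301	166	174
DQA10501-DQB10301	167	175
DQA10501-DQB10301	169	177
DQA10501-DQB10301	172	180
DQA10501-DQB10301	192	200
DQA10501-DQB10301	195	203
DQA10501-DQB10301	203	211
DQA10501-DQB10301	205	213
DQA10501-DQB10301	206	214
DQA10501-DQB10301	207	215
DQA10501-DQB10301	213	221
DQA10501-DQB10301	215	233
DQA10501-DQB10301	228	236
DQA10501-DQB10301	230	238
DQA10501-DQB10301	232	240
DQA10501-DQB10301	237	245
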