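DRB1*01:01	5	13
DRB1*01:01	11	19
DRB1*01:01	10	18
DRB1*01:01	13	21
DRB1*01:01	24	32
DRB1*01:01	26	34
DRB1*01:01	39	47
DRB1*01:01	46	54
DRB1*01:01	50	58
DRB1*01:01	53	61
DRB1*01:01	57	65
DRB1*01:01	58	66
DRB1*01:01	60	68
DRB1*01:01	66	74
DRB1*01:01	73	81
DRB1*01:01	82	90
DRB1*01:01	89	97
DRB1*01:01	90	98
DRB1*01:01	104	112
DRB1*01:01	107	115
DRB1*01:01	114	122
DRB1*01:01	119	127
DRB1*01:01	122	130
DRB1*01:01	143	151
DRB1*01:01	142	150
DRB1*01:01	156	164
DRB1*01:01	157	165
DRB1*01:01	161	169
DRB1*01:01	163	171
DRB1*01:01	167	175
DRB1*01:01	187	195
DRB1*01:01	190	198
DRB1*01:01	191	199
DRB1*01:01	195	203
DRB1*01:01	197	205
DRB1*01:01	203	211
DRB1*01:01	205	213
DRB1*01:01	227	235
DRB1*01:01	228	236
DRB1*01:01	232	240
DRB1*01:01	235	243
DRB1*01:01	239	247
DRB3*01:01	53	61
DRB3*01:01	66	74
DRB3*01:01	81	89
DRB3*01:01	191	199
DRB4*01:01	26	34
DRB4*01:01	38	46
DRB4*01:01	46	54
DRB4*01:01	48	56
DRB4*01:01	50	58
DRB4*01:01	107	115
DRB4*01:01	142	150
DRB4*01:01	158	166
DRB4*01:01	160	168
DRB4*01:01	238	246
DRB4*01:01	239	247
DRB5*01:01	5	13
DRB5*01:01	11	19
DRB5*01:01	13	21
DRB5*01:01	20	28
DRB5*01:01	24	32
DRB5*01:01	26	34
DRB5*01:01	39	47
DRB5*01:01	46	54
DRB5*01:01	59	67
DRB5*01:01	66	74
DRB5*01:01	73	81
DRB5*01:01	89	97
DRB5*01:01	90	98
DRB5*01:01	143	151
DRB5*01:01	146	154
DRB5*01:01	150	158
DRB5*01:01	163	171
DRB5*01:01	165	173
DRB5*01:01	166	174
DRB5*01:01	203	211
DRB5*01:01	228	236
DRB5*01:01	238	246
DRB5*01:01	239	247
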