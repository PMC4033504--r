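DNAStar	11	19
DNAStar	28	35
DNAStar	68	77
DNAStar	95	111
DNAStar	130	139
DNAStar	173	187
DNAStar	193	197
DNAStar	211	225
BPAP	20	26
BPAP	32	52
BPAP	54	70
BPAP	86	93
BPAP	138	168
BPAP	175	209
BPAP	218	242
BepiPred	11	18
BepiPred	30	34
BepiPred	71	78
BepiPred	99	107
BepiPred	132	138
BepiPred	168	183
BepiPred	194	199
BepiPred	210	224
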