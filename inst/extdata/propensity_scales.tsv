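scale	residue	value
parker	A	2.1
parker	C	1.4
parker	D	10.0
parker	E	7.8
parker	F	-9.2
parker	G	5.7
parker	H	2.1
parker	I	-8.0
parker	K	5.7
parker	L	-9.2
parker	M	-4.2
parker	N	7.0
parker	P	2.1
parker	Q	6.0
parker	R	4.2
parker	S	6.5
parker	T	5.2
parker	V	-3.7
parker	W	-10.0
parker	Y	-1.9
hopp_woods	A	-0.5
hopp_woods	C	-1.0
hopp_woods	D	3.0
hopp_woods	E	3.0
hopp_woods	F	-2.5
hopp_woods	G	0.0
hopp_woods	H	-0.5
hopp_woods	I	-1.8
hopp_woods	K	3.0
hopp_woods	L	-1.8
hopp_woods	M	-1.3
hopp_woods	N	0.2
hopp_woods	P	0.0
hopp_woods	Q	0.2
hopp_woods	R	3.0
hopp_woods	S	0.3
hopp_woods	T	-0.4
hopp_woods	V	-1.5
hopp_woods	W	-3.4
hopp_woods	Y	-2.3
emini	A	0.815
emini	C	0.394
emini	D	1.283
emini	E	1.445
emini	F	0.695
emini	G	0.714
emini	H	1.18
emini	I	0.603
emini	K	1.545
emini	L	0.603
emini	M	0.714
emini	N	1.296
emini	P	1.236
emini	Q	1.348
emini	R	1.475
emini	S	1.115
emini	T	1.184
emini	V	0.606
emini	W	0.808
emini	Y	0.689
karplus_schulz	A	0.984
karplus_schulz	C	0.906
karplus_schulz	D	1.068
karplus_schulz	E	1.094
karplus_schulz	F	0.915
karplus_schulz	G	1.031
karplus_schulz	H	0.95
karplus_schulz	I	0.927
karplus_schulz	K	1.102
karplus_schulz	L	0.935
karplus_schulz	M	0.952
karplus_schulz	N	1.048
karplus_schulz	P	1.049
karplus_schulz	Q	1.037
karplus_schulz	R	1.008
karplus_schulz	S	1.046
karplus_schulz	T	0.997
karplus_schulz	V	0.931
karplus_schulz	W	0.904
karplus_schulz	Y	0.929
kolaskar_tongaonkar	A	1.064
kolaskar_tongaonkar	C	1.412
kolaskar_tongaonkar	D	0.866
kolaskar_tongaonkar	E	0.851
kolaskar_tongaonkar	F	1.091
kolaskar_tongaonkar	G	0.874
kolaskar_tongaonkar	H	1.105
kolaskar_tongaonkar	I	1.152
kolaskar_tongaonkar	K	0.93
kolaskar_tongaonkar	L	1.25
kolaskar_tongaonkar	M	0.826
kolaskar_tongaonkar	N	0.776
kolaskar_tongaonkar	P	1.064
kolaskar_tongaonkar	Q	1.015
kolaskar_tongaonkar	R	0.873
kolaskar_tongaonkar	S	1.012
kolaskar_tongaonkar	T	0.909
kolaskar_tongaonkar	V	1.383
kolaskar_tongaonkar	W	0.893
kolaskar_tongaonkar	Y	1.161
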