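# Per-residue propensity scales for linear B-cell epitope prediction.
# Values are the published literature scales (approximate to the precision
# commonly reproduced in prediction servers):
#   parker_hydrophilicity        Parker, Guo & Hodges (1986) HPLC hydrophilicity
#   emini_accessibility          Emini et al. (1985) surface probability fractions
#   karplus_schulz_flexibility   Karplus & Schulz (1985) normalized B-factors
#   kolaskar_tongaonkar_antigenicity  Kolaskar & Tongaonkar (1990) antigenic propensity
#   chou_fasman_turns            Chou & Fasman (1978) beta-turn conformational parameter
#   ponnuswamy_polarity          negated Ponnuswamy et al. (1980) average surrounding
#                                hydrophobicity (higher = more polar/exposed)
#   janin_exposure               negated Janin (1979) buried->exposed transfer energy
#                                (higher = more exposed)
scale	residue	value
parker_hydrophilicity	A	2.1
parker_hydrophilicity	R	4.2
parker_hydrophilicity	N	7.0
parker_hydrophilicity	D	10.0
parker_hydrophilicity	C	1.4
parker_hydrophilicity	Q	6.0
parker_hydrophilicity	E	7.8
parker_hydrophilicity	G	5.7
parker_hydrophilicity	H	2.1
parker_hydrophilicity	I	-8.0
parker_hydrophilicity	L	-9.2
parker_hydrophilicity	K	5.7
parker_hydrophilicity	M	-4.2
parker_hydrophilicity	F	-9.2
parker_hydrophilicity	P	2.1
parker_hydrophilicity	S	6.5
parker_hydrophilicity	T	5.2
parker_hydrophilicity	W	-10.0
parker_hydrophilicity	Y	-1.9
parker_hydrophilicity	V	-3.7
emini_accessibility	A	0.49
emini_accessibility	R	0.95
emini_accessibility	N	0.81
emini_accessibility	D	0.78
emini_accessibility	C	0.26
emini_accessibility	Q	0.84
emini_accessibility	E	0.84
emini_accessibility	G	0.48
emini_accessibility	H	0.66
emini_accessibility	I	0.34
emini_accessibility	L	0.40
emini_accessibility	K	0.97
emini_accessibility	M	0.48
emini_accessibility	F	0.42
emini_accessibility	P	0.75
emini_accessibility	S	0.65
emini_accessibility	T	0.70
emini_accessibility	W	0.51
emini_accessibility	Y	0.76
emini_accessibility	V	0.36
karplus_schulz_flexibility	A	1.041
karplus_schulz_flexibility	R	1.038
karplus_schulz_flexibility	N	1.117
karplus_schulz_flexibility	D	1.033
karplus_schulz_flexibility	C	0.960
karplus_schulz_flexibility	Q	1.165
karplus_schulz_flexibility	E	1.094
karplus_schulz_flexibility	G	1.142
karplus_schulz_flexibility	H	0.982
karplus_schulz_flexibility	I	0.892
karplus_schulz_flexibility	L	0.967
karplus_schulz_flexibility	K	1.093
karplus_schulz_flexibility	M	0.947
karplus_schulz_flexibility	F	0.930
karplus_schulz_flexibility	P	1.055
karplus_schulz_flexibility	S	1.169
karplus_schulz_flexibility	T	1.073
karplus_schulz_flexibility	W	0.925
karplus_schulz_flexibility	Y	0.961
karplus_schulz_flexibility	V	0.982
kolaskar_tongaonkar_antigenicity	A	1.064
kolaskar_tongaonkar_antigenicity	R	0.873
kolaskar_tongaonkar_antigenicity	N	0.776
kolaskar_tongaonkar_antigenicity	D	0.866
kolaskar_tongaonkar_antigenicity	C	1.412
kolaskar_tongaonkar_antigenicity	Q	1.015
kolaskar_tongaonkar_antigenicity	E	0.851
kolaskar_tongaonkar_antigenicity	G	0.874
kolaskar_tongaonkar_antigenicity	H	1.105
kolaskar_tongaonkar_antigenicity	I	1.152
kolaskar_tongaonkar_antigenicity	L	1.250
kolaskar_tongaonkar_antigenicity	K	0.930
kolaskar_tongaonkar_antigenicity	M	0.826
kolaskar_tongaonkar_antigenicity	F	1.091
kolaskar_tongaonkar_antigenicity	P	1.064
kolaskar_tongaonkar_antigenicity	S	1.012
kolaskar_tongaonkar_antigenicity	T	0.909
kolaskar_tongaonkar_antigenicity	W	0.893
kolaskar_tongaonkar_antigenicity	Y	1.161
kolaskar_tongaonkar_antigenicity	V	1.383
chou_fasman_turns	A	0.66
chou_fasman_turns	R	0.95
chou_fasman_turns	N	1.56
chou_fasman_turns	D	1.46
chou_fasman_turns	C	1.19
chou_fasman_turns	Q	0.98
chou_fasman_turns	E	0.74
chou_fasman_turns	G	1.56
chou_fasman_turns	H	0.95
chou_fasman_turns	I	0.47
chou_fasman_turns	L	0.59
chou_fasman_turns	K	1.01
chou_fasman_turns	M	0.60
chou_fasman_turns	F	0.60
chou_fasman_turns	P	1.52
chou_fasman_turns	S	1.43
chou_fasman_turns	T	0.96
chou_fasman_turns	W	0.96
chou_fasman_turns	Y	1.14
chou_fasman_turns	V	0.50
ponnuswamy_polarity	A	-12.97
ponnuswamy_polarity	R	-11.72
ponnuswamy_polarity	N	-11.42
ponnuswamy_polarity	D	-10.85
ponnuswamy_polarity	C	-14.63
ponnuswamy_polarity	Q	-11.76
ponnuswamy_polarity	E	-11.89
ponnuswamy_polarity	G	-12.43
ponnuswamy_polarity	H	-12.16
ponnuswamy_polarity	I	-15.67
ponnuswamy_polarity	L	-14.90
ponnuswamy_polarity	K	-11.36
ponnuswamy_polarity	M	-14.39
ponnuswamy_polarity	F	-14.00
ponnuswamy_polarity	P	-11.37
ponnuswamy_polarity	S	-11.23
ponnuswamy_polarity	T	-11.69
ponnuswamy_polarity	W	-13.93
ponnuswamy_polarity	Y	-13.42
ponnuswamy_polarity	V	-15.71
janin_exposure	A	-0.3
janin_exposure	R	1.4
janin_exposure	N	0.5
janin_exposure	D	0.6
janin_exposure	C	-0.9
janin_exposure	Q	0.7
janin_exposure	E	0.7
janin_exposure	G	-0.3
janin_exposure	H	0.1
janin_exposure	I	-0.7
janin_exposure	L	-0.5
janin_exposure	K	1.8
janin_exposure	M	-0.4
janin_exposure	F	-0.5
janin_exposure	P	0.3
janin_exposure	S	0.1
janin_exposure	T	0.2
janin_exposure	W	-0.3
janin_exposure	Y	0.4
janin_exposure	V	-0.6
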