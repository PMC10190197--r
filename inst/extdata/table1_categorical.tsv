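variable	level	nr	r	r_bp
sex	female	172	188	14
sex	male	19	24	2
ama	negative	16	13	2
ama	positive	136	163	13
sequestrants	no	178	206	13
sequestrants	yes	13	6	3
antibiotics	no	150	177	12
antibiotics	yes	41	35	4
apap	no	181	199	15
apap	yes	10	13	1
statins	no	164	179	13
statins	yes	27	33	3
ppi	no	141	138	9
ppi	yes	50	74	7
alcohol	abstinent	64	71	5
alcohol	moderate	115	128	11
alcohol	excess	12	13	0
smoking	never	77	75	5
smoking	former	98	116	10
smoking	current	16	21	1
celiac	yes	4	2	2
celiac	no	187	210	14
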