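variable	group	n	mean	sd
age	NR	191	61.97	10.69
age	R	212	64.47	9.99
age	R_BP	16	66.81	7.70
bmi	NR	191	27.62	6.12
bmi	R	212	28.68	6.23
bmi	R_BP	16	27.01	4.58
albumin	NR	191	40.17	4.85
albumin	R	212	41.11	4.24
albumin	R_BP	16	38.62	4.54
udca_dose	NR	191	13.15	3.58
udca_dose	R	212	12.30	3.46
udca_dose	R_BP	16	12.37	4.19
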