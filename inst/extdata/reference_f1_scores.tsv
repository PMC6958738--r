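features	dataset	non-malignant	DCIS	IDC
signature	1	0.93	1.00	0.92
signature	2	1.00	1.00	1.00
signature	3	0.97	1.00	0.95
signature	4	1.00	1.00	1.00
signature	Avg	0.97	1.00	0.96
all	1	0.95	0.98	0.97
all	2	0.98	1.00	0.97
all	3	1.00	1.00	1.00
all	4	1.00	1.00	1.00
all	Avg	0.98	0.99	0.98
unsupervised	1	0.96	0.97	0.93
unsupervised	2	0.96	0.91	0.92
unsupervised	3	0.95	0.96	0.86
unsupervised	4	0.96	0.97	0.93
unsupervised	Avg	0.95	0.95	0.91
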