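annotation	dataset	non-malignant	DCIS	IDC
manual	1	20	21	20
manual	2	20	18	17
manual	3	15	17	10
manual	4	13	10	13
automatic	1	133	34	75
automatic	2	152	36	53
automatic	3	165	24	63
automatic	4	147	34	63
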