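gene	n_up	n_down	complex
NDUFB4	0	1	I
NDUFB6	0	1	I
NDUFB7	1	0	I
NDUFB9	0	1	I
NDUFS4	0	1	I
UQCRFS1	0	1	III
UQCR11	1	0	III
COX6A1	1	1	IV
COX7A1	0	2	IV
ATP5E	2	0	V
ATP5G3	0	1	V
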