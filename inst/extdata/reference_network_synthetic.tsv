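# Synthetic stand-in reference network: 50 directed signed edges over the 9 functional cytokine sets.
source	target	sign	weight	confidence	provenance
CK1	CK2	-1	1	0.88	synthetic stand-in
CK1	MK15	-1	1	0.85	synthetic stand-in
CK1	MK1A	1	1	0.92	synthetic stand-in
CK1	MK1B	1	1	0.84	synthetic stand-in
CK1	MK23	1	1	0.92	synthetic stand-in
CK1	MK6	1	1	0.84	synthetic stand-in
CK17	CK2	-1	1	0.81	synthetic stand-in
CK17	MK15	1	1	0.95	synthetic stand-in
CK17	MK1A	1	1	0.93	synthetic stand-in
CK17	MK1B	1	1	0.93	synthetic stand-in
CK17	MK2	-1	1	0.97	synthetic stand-in
CK17	MK23	-1	1	0.87	synthetic stand-in
CK17	MK6	1	1	0.86	synthetic stand-in
CK2	CK1	-1	1	0.89	synthetic stand-in
CK2	MK15	1	1	0.87	synthetic stand-in
CK2	MK1A	1	1	0.93	synthetic stand-in
CK2	MK1B	1	1	0.91	synthetic stand-in
CK2	MK23	1	1	0.81	synthetic stand-in
CK2	MK6	-1	1	0.91	synthetic stand-in
MK15	CK1	1	1	0.92	synthetic stand-in
MK15	CK17	1	1	0.86	synthetic stand-in
MK15	MK1A	1	1	0.95	synthetic stand-in
MK15	MK1B	1	1	0.91	synthetic stand-in
MK15	MK6	1	1	0.82	synthetic stand-in
MK1A	CK17	1	1	0.81	synthetic stand-in
MK1A	MK15	-1	1	0.99	synthetic stand-in
MK1A	MK2	1	1	0.8	synthetic stand-in
MK1A	MK23	1	1	0.87	synthetic stand-in
MK1A	MK6	1	1	0.84	synthetic stand-in
MK1B	CK17	1	1	0.89	synthetic stand-in
MK1B	MK15	-1	1	0.88	synthetic stand-in
MK1B	MK2	1	1	0.92	synthetic stand-in
MK1B	MK23	1	1	0.88	synthetic stand-in
MK1B	MK6	1	1	0.95	synthetic stand-in
MK2	CK1	-1	1	0.9	synthetic stand-in
MK2	MK15	-1	1	0.86	synthetic stand-in
MK2	MK1A	-1	1	0.86	synthetic stand-in
MK2	MK1B	-1	1	0.84	synthetic stand-in
MK2	MK23	1	1	0.87	synthetic stand-in
MK2	MK6	-1	1	0.88	synthetic stand-in
MK23	CK1	1	1	0.99	synthetic stand-in
MK23	CK17	1	1	0.82	synthetic stand-in
MK23	MK1A	-1	1	0.81	synthetic stand-in
MK23	MK1B	-1	1	0.93	synthetic stand-in
MK23	MK2	1	1	0.83	synthetic stand-in
MK6	CK17	1	1	0.98	synthetic stand-in
MK6	CK2	1	1	0.98	synthetic stand-in
MK6	MK1A	-1	1	0.88	synthetic stand-in
MK6	MK1B	-1	1	0.99	synthetic stand-in
MK6	MK2	1	1	0.96	synthetic stand-in
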