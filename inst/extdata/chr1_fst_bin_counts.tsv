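label	lo	hi	shared	new_nonsyn	new_syn
>=0.95-1	0.95	1.00	204	9	6
0.9-0.95	0.90	0.95	45	6	5
0.8-0.9	0.80	0.90	59	8	11
0.7-0.8	0.70	0.80	52	14	7
0.6-0.7	0.60	0.70	37	10	14
0.5-0.6	0.50	0.60	45	12	8
0.4-0.5	0.40	0.50	41	18	9
0.3-0.4	0.30	0.40	32	17	8
0.25-0.3	0.25	0.30	17	21	12
<0.25	0.00	0.25	155	0	0
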