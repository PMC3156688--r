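gene	ps_m_microarray	ps_m	ps_pn	published_effect_pct
CG14629	0.72	1.02	0.91	89
CG3655	0.92	1.69	0.40	24
CG14805	2.03	3.80	0.81	21
CG14806	0.45	1.34	0.23	17
Notch	1.29	1.71	0.18	11
dunce	0.93	2.07	0.88	43
Cdc42	1.63	1.39	0.70	50
CG12703	1.73	1.77	0.68	38
Cyp6v1	0.56	0.89	1.10	124
CG1835	-0.81	-0.29	0.03	-9
penguin	1.68	4.09	0.86	21
Helicase	1.90	2.60	1.08	42
All genes	1.09	1.84	0.66	36
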