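mirna	M_mcf_4h	M_mcf_24h	M_hct_4h	M_hct_24h	flag_mcf10a	flag_hct116	max_m
miR-34c-5p	2.37	3.98	0.59	3.54	1	1	3.98
1947411_x4	0.37	0.95	0.59	2.65	1	1	2.65
miR-486-5p	Inf	Inf	0.58	1.95	1	1	1.95
miR-148a-3p	1.1	1.77	0.71	1.26	1	1	1.77
miR-152	0.33	0.85	0.23	1.76	1	1	1.76
miR-1247-3p	NA	NA	0.53	1.69	0	1	1.69
miR-1	1.23	0.98	0.77	1.58	1	1	1.58
let-7a-3p	1.55	0.49	0.89	0.5	1	1	1.55
miR-365a-3p	0.91	0.16	0.47	1.43	1	1	1.43
miR-3184-3p	1.1	0.3	0.21	1.39	1	1	1.39
miR-423-5p	1.1	0.3	0.21	1.39	1	1	1.39
miR-139-5p	1	-1	0.4	1.23	0	1	1.23
miR-125b-5p	-0.54	0.89	1.02	0.87	0	1	1.02
miR-191-5p	0.04	0.29	0.17	0.97	0	1	0.97
miR-34a-5p	0.47	0.77	0.32	0.97	1	1	0.97
miR-96-5p	0.96	0.93	0.51	0.4	1	0	0.96
miR-192-5p	0.18	0.44	0.4	0.93	0	1	0.93
miR-215	0.19	0.46	0.4	0.93	0	1	0.93
miR-148b-3p	0.28	0.26	0.43	0.84	0	1	0.84
miR-146a-5p	-0.64	-0.6	0.16	0.84	0	1	0.84
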