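scenario	trait	model	sigma_a	sigma_a_se	sigma_d	sigma_d_se	sigma_aa	sigma_aa_se	sigma_eps	sigma_eps_se	het_b	het_b_se	loglik
1	TCH	A	98.13	3.64	NA	NA	NA	NA	36.09	0.39	NA	NA	-45439.59
1	TCH	AH	95.78	3.56	NA	NA	NA	NA	36.09	0.39	125.72	19.88	-45416.81
1	TCH	AD	49.91	5.21	35.84	4.70	NA	NA	36.08	0.39	NA	NA	-45403.70
1	TCH	ADH	53.41	5.33	31.70	4.63	NA	NA	36.08	0.39	133.89	29.95	-45390.63
1	TCH	ADE	21.91	4.19	9.71	4.19	44.33	5.43	36.06	0.39	NA	NA	-45373.39
1	TCH	ADEH	23.00	4.22	3.13	3.68	48.45	5.30	36.06	0.39	118.83	20.66	-45355.42
1	CCS	A	0.41	0.02	NA	NA	NA	NA	0.134	0.001	NA	NA	6586.014
1	CCS	AH	0.41	0.02	NA	NA	NA	NA	0.134	0.001	0.093	1.30	6586.277
1	CCS	AD	0.40	0.02	0.006	0.014	NA	NA	0.134	0.001	NA	NA	6586.060
1	CCS	ADH	0.40	0.02	0.008	0.014	NA	NA	0.134	0.001	0.142	1.36	6586.363
1	CCS	ADE	0.256	0.03	0	NA	0.110	0.02	0.134	0.002	NA	NA	6596.317
1	CCS	ADEH	0.256	0.03	0	NA	0.11	0.02	0.134	0.002	0.204	1.30	6596.591
1	Fibre	A	1.54	0.05	NA	NA	NA	NA	0.16	0.002	NA	NA	4118.252
1	Fibre	AH	1.54	0.05	NA	NA	NA	NA	0.16	0.002	1.29	2.47	4119.29
1	Fibre	AD	1.43	0.08	0.08	0.05	NA	NA	0.16	0.002	NA	NA	4119.76
1	Fibre	ADH	1.43	0.08	0.08	0.05	NA	NA	0.16	0.002	0.921	2.78	4120.84
1	Fibre	ADE	1.14	0.12	0.01	0.05	0.28	0.10	0.16	0.002	NA	NA	4123.30
1	Fibre	ADEH	1.14	0.12	0.01	0.05	0.27	0.10	0.16	0.002	0.841	2.53	4124.28
2	TCH	A	85.99	2.75	NA	NA	NA	NA	37.39	0.33	NA	NA	-66907.76
2	TCH	AH	83.26	2.67	NA	NA	NA	NA	37.39	0.33	139.70	16.78	-66870.77
2	TCH	AD	48.84	4.14	29.59	3.80	NA	NA	37.38	0.33	NA	NA	-66872.13
2	TCH	ADH	53.52	4.25	23.87	3.70	NA	NA	37.38	0.33	157.38	25.40	-66850.68
2	TCH	ADE	22.82	3.72	11.09	3.49	38.89	4.82	37.37	0.33	NA	NA	-66845.05
2	TCH	ADEH	23.30	3.67	1.24	2.67	46.47	4.54	37.37	0.33	140.57	17.01	-66813.82
2	CCS	A	0.367	0.012	NA	NA	NA	NA	0.125	0.001	NA	NA	10890.366
2	CCS	AH	0.367	0.012	NA	NA	NA	NA	0.125	0.001	-0.801	1.106	10890.728
2	CCS	AD	0.338	0.019	0.021	0.012	NA	NA	0.125	0.001	NA	NA	10891.675
2	CCS	ADH	0.338	0.019	0.022	0.012	NA	NA	0.125	0.001	-0.764	1.27	10892.093
2	CCS	ADE	0.228	0.024	0	NA	0.110	0.019	0.125	0.001	NA	NA	10903.98
2	CCS	ADEH	0.228	0.024	0	NA	0.109	0.019	0.125	0.001	-0.811	1.11	10904.35
2	Fibre	A	1.38	0.04	NA	NA	NA	NA	0.16	0.001	NA	NA	6449.904
2	Fibre	AH	1.38	0.04	NA	NA	NA	NA	0.16	0.001	0.562	2.12	6450.688
2	Fibre	AD	1.31	0.06	0.05	0.04	NA	NA	0.16	0.001	NA	NA	6450.904
2	Fibre	ADH	1.31	0.06	0.06	0.04	NA	NA	0.16	0.001	0.445	2.34	6451.769
2	Fibre	ADE	1.13	0.10	0.02	0.04	0.18	0.09	0.16	0.001	NA	NA	6452.861
2	Fibre	ADEH	1.13	0.10	0.02	0.04	0.18	0.09	0.16	0.001	0.263	2.21	6453.659
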