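scenario	model	TCH	CCS	Fibre
1a	A	0.248	0.405	0.445
1a	AH	0.291	0.404	0.446
1a	AD	0.264	0.406	0.442
1a	ADH	0.287	0.406	0.442
1a	ADE	0.283	0.409	0.443
1a	ADEH	0.325	0.408	0.444
1a	RKHS	0.272	0.390	0.407
1b	A	0.218	0.297	0.396
1b	AH	0.255	0.297	0.395
1b	AD	0.235	0.304	0.390
1b	ADH	0.258	0.305	0.390
1b	ADE	0.257	0.315	0.394
1b	ADEH	0.286	0.315	0.393
1b	RKHS	0.246	0.318	0.389
2	A	0.247	0.348	0.431
2	AH	0.280	0.347	0.431
2	AD	0.262	0.353	0.429
2	ADH	0.280	0.352	0.429
2	ADE	0.270	0.354	0.429
2	ADEH	0.290	0.354	0.428
2	RKHS	0.247	0.348	0.431
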