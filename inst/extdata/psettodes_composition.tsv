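accession	partition	size	pct_A	pct_T	pct_G	pct_C	pct_AT	at_skew	gc_skew
OR231239	whole	16747	28.09	26.06	16.24	29.56	54.15	0.037	-0.291
FJ606835	whole	17315	28.83	24.78	15.71	30.68	53.61	0.076	-0.323
AP006835	whole	16683	28.57	24.50	15.78	31.15	53.07	0.077	-0.328
OR231239	PCGs	11427	25.00	27.73	16.00	31.27	52.74	-0.052	-0.323
FJ606835	PCGs	11427	25.37	25.75	15.62	33.25	51.13	-0.008	-0.361
AP006835	PCGs	11426	25.33	25.62	15.62	33.43	50.95	-0.006	-0.363
OR231239	rRNAs	2689	31.42	21.38	21.87	25.33	52.81	0.190	-0.073
FJ606835	rRNAs	2680	32.43	20.56	20.86	26.16	52.99	0.224	-0.113
AP006835	rRNAs	2680	32.43	20.45	20.90	26.23	52.87	0.227	-0.113
OR231239	tRNAs	1556	27.83	27.31	23.14	21.72	55.14	0.009	0.032
FJ606835	tRNAs	1553	27.17	26.85	23.82	22.15	54.02	0.006	0.036
AP006835	tRNAs	1554	27.28	26.83	23.68	22.20	54.12	0.008	0.032
OR231239	CRs	1015	30.25	33.40	12.51	23.84	63.65	-0.050	-0.312
FJ606835	CRs	1601	38.91	33.92	10.31	16.86	72.83	0.069	-0.241
AP006835	CRs	968	42.15	36.36	7.13	14.36	78.51	0.074	-0.337
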