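property	AA	AC	AG	AT	CA	CC	CG	CT	GA	GC	GG	GT	TA	TC	TG	TT
Twist	31.57	33.38	32.75	36.81	31.27	36.82	32.54	35.47	38.91	33.36	38.19	38.08	31.53	37.33	36.06	36.76
Tilt	 2.07	-1.34	 0.56	 0.05	 1.09	 1.46	 1.04	-2.85	 2.65	-0.11	-3.36	  2.1	-0.02	-2.26	 2.52	-0.56
Roll	-0.66	-0.96	 7.95	 5.08	 5.88	 5.73	 8.27	  7.3	 7.87	 6.39	 7.39	 1.37	-3.33	 7.22	 1.43	 3.16
Shift	0.171	-0.149	0.067	-0.141	 0.13	-0.004	 0.29	0.239	-0.291	-0.283	0.004	-0.143	 0.06	0.078	-0.126	-0.185
Slide	-0.701	-0.644	-0.912	-0.617	0.424	0.576	-1.195	0.889	 0.45	0.009	-0.185	 0.86	-0.499	 0.47	-0.109	 -0.9
Rise	 3.58	3.462	 3.34	3.373	 3.59	3.405	3.153	3.109	3.307	 3.19	3.158	3.565	3.482	3.586	3.234	3.556
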