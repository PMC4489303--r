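property	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
SYNTHETIC-AA-001	1.782	-0.395	-0.703	1.278	0.308	-0.02	0.544	-0.537	-0.018	-0.092	0.061	-0.065	  0.3	-1.903	0.636	-1.406	-0.636	-0.665	0.551	0.367
SYNTHETIC-AA-002	1.343	0.641	 1.18	-1.51	-0.439	-2.22	0.976	0.511	1.296	0.943	1.365	-0.733	-1.374	-1.152	-0.668	-0.522	-0.698	1.665	-0.317	1.325
SYNTHETIC-AA-003	 2.16	0.129	0.746	-1.274	0.343	-0.787	-0.164	 0.62	-0.955	0.317	-0.025	-0.243	0.931	-0.273	-0.933	-0.103	-1.982	0.711	-0.293	  0.6
SYNTHETIC-AA-004	0.865	0.656	1.526	-0.625	-1.756	 0.24	 0.85	0.095	-2.093	0.292	0.551	1.523	-1.407	0.309	-0.535	-0.49	-0.08	0.434	-0.911	-0.864
SYNTHETIC-AA-005	-0.364	0.287	-1.263	-0.07	0.184	-0.881	 2.16	1.036	0.817	1.257	0.915	-0.88	-1.272	-0.323	-1.458	0.939	-0.496	1.354	-1.098	-0.308
SYNTHETIC-AA-006	0.597	0.675	-0.057	-0.525	-0.014	1.609	0.844	1.331	0.827	-1.498	0.219	-0.266	1.301	0.355	0.079	-0.861	-0.309	0.703	0.847	1.162
SYNTHETIC-AA-007	1.242	-0.424	-1.375	0.915	-0.409	0.337	-0.537	0.394	0.379	1.884	0.306	-2.383	-1.71	-0.718	1.694	-1.067	0.191	 0.19	-0.089	-1.589
SYNTHETIC-AA-008	0.319	-0.529	0.217	0.605	-0.005	-0.47	-0.308	1.122	0.293	-0.004	-0.26	-0.091	0.422	0.105	0.304	1.342	0.237	0.804	-0.684	1.809
SYNTHETIC-AA-009	-0.763	-0.304	0.353	-0.404	-0.354	-1.296	0.753	0.287	 -0.2	-1.518	-0.959	-2.293	-0.227	-1.083	0.347	-0.616	-0.358	-0.485	1.098	-0.323
SYNTHETIC-AA-010	-0.108	0.906	-1.768	-0.011	0.461	-1.776	0.662	0.359	-0.733	1.104	-0.233	-0.714	1.615	0.525	0.578	2.118	-1.31	-1.467	-1.234	-1.13
SYNTHETIC-AA-011	0.468	-3.282	0.738	1.191	-0.133	0.208	 2.24	0.113	1.034	1.241	-2.049	-0.779	-0.292	-0.143	-0.29	0.305	-0.974	0.268	1.903	-0.383
SYNTHETIC-AA-012	-0.692	0.481	-2.192	0.445	 0.61	0.279	-0.354	1.611	2.141	-0.583	-1.058	-0.43	0.286	-1.203	-1.638	-0.304	-0.787	0.726	 0.54	1.565
SYNTHETIC-AA-013	0.536	-0.349	0.585	0.902	 0.89	-0.865	-0.91	-0.437	-0.095	-0.946	1.371	-2.171	-0.071	-0.989	0.358	0.808	-1.006	-0.365	-0.189	1.717
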