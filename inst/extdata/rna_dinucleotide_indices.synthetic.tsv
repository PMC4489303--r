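property	AA	AC	AG	AU	CA	CC	CG	CU	GA	GC	GG	GU	UA	UC	UG	UU
Twist-RNA	29.48	31.23	31.15	29.12	28.14	33.72	31.18	34.76	34.94	32.21	30.81	30.14	34.21	30.55	33.78	34.46
Tilt-RNA	-1.81	 3.71	-0.44	 1.01	-2.46	  0.6	 1.58	 1.82	-0.38	 3.89	-2.53	 0.88	 1.61	  0.3	-0.79	 1.78
Roll-RNA	 5.43	 6.23	 3.62	10.82	 5.78	 2.39	 7.21	  7.5	 3.88	11.01	 5.31	10.77	 7.57	 5.88	10.16	 11.8
Shift-RNA	0.146	-0.098	-0.243	-0.143	 0.14	0.193	0.104	0.297	-0.014	-0.094	0.036	-0.116	-0.091	0.115	-0.168	0.125
Slide-RNA	-1.244	-1.815	-1.039	-1.375	-1.186	-1.244	-1.784	-1.751	-1.513	-1.064	-1.514	-1.202	-1.897	-1.996	-1.233	-1.358
Rise-RNA	3.355	3.437	2.828	2.866	3.059	3.056	3.031	3.224	3.175	3.437	3.215	2.808	2.821	3.356	3.149	2.844
SYNTH-RNA-DI-001	-2.272	2.023	1.029	0.108	-0.533	-0.548	 0.01	-0.625	0.246	0.019	0.115	0.795	-0.624	-1.941	-1.173	-0.14
SYNTH-RNA-DI-002	0.453	0.191	-0.996	-0.073	-1.171	1.493	1.338	1.615	1.986	 0.63	2.331	0.324	0.467	1.357	 1.37	0.328
SYNTH-RNA-DI-003	0.786	-1.309	0.303	1.816	-1.333	-0.004	0.972	-0.179	1.604	1.394	0.235	-0.563	0.385	-0.206	0.312	1.488
SYNTH-RNA-DI-004	 0.45	-0.77	-0.171	-1.195	1.803	-0.129	0.375	0.373	0.766	0.719	-0.72	1.582	-1.487	0.597	1.244	1.241
SYNTH-RNA-DI-005	-0.094	0.468	0.274	0.544	0.725	-0.308	0.764	-1.366	0.247	0.292	0.552	-0.371	0.408	-0.736	 0.91	0.425
SYNTH-RNA-DI-006	-0.059	-1.051	-1.751	-0.607	0.674	-0.59	0.952	-0.547	-0.639	-0.179	1.148	-0.047	-0.101	-0.237	1.697	-0.923
SYNTH-RNA-DI-007	1.367	0.963	1.128	0.445	1.311	1.006	-0.68	-1.175	 0.73	-1.244	-0.664	-0.387	-0.126	-2.054	0.994	-0.096
SYNTH-RNA-DI-008	-0.326	-1.572	0.807	1.109	-0.313	-0.581	-0.911	1.791	-3.319	-1.077	-0.827	0.327	1.112	0.427	0.333	0.655
SYNTH-RNA-DI-009	-1.393	0.596	-0.869	-0.208	1.095	-0.743	0.463	1.425	0.403	2.296	0.993	 -0.4	-0.732	0.074	 -0.3	-1.017
SYNTH-RNA-DI-010	-0.344	-0.258	0.845	0.245	  0.2	-0.43	-1.759	-0.417	-0.542	-0.468	0.877	0.272	0.451	-0.392	-0.263	-0.568
SYNTH-RNA-DI-011	-1.308	3.019	1.242	0.864	1.459	0.033	-1.279	0.404	-0.458	-0.939	-2.158	-2.053	-2.396	-0.648	0.458	-0.934
SYNTH-RNA-DI-012	0.228	-0.039	-0.603	0.201	0.814	-0.507	-0.232	-0.419	-0.892	-0.573	-0.092	-0.381	0.835	0.497	-0.142	-2.029
SYNTH-RNA-DI-013	0.116	-0.617	-2.758	0.155	-0.195	1.396	-0.042	0.787	-0.813	-0.909	1.122	0.082	1.363	-2.663	-0.628	 -1.5
SYNTH-RNA-DI-014	0.881	1.772	-1.946	2.093	  0.2	-0.731	0.609	-0.181	 -1.6	 0.23	0.738	-1.523	-0.562	-0.968	0.053	-0.904
SYNTH-RNA-DI-015	-0.147	-0.791	-0.564	1.832	0.666	0.656	-0.32	-0.173	0.214	-0.291	0.689	0.539	0.346	-0.09	0.348	-1.077
SYNTH-RNA-DI-016	1.573	1.458	-0.838	0.237	0.067	-1.206	1.391	-1.252	-0.41	-0.437	0.397	-1.237	-1.08	0.094	-1.652	0.911
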