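property	AAA	AAC	AAG	AAT	ACA	ACC	ACG	ACT	AGA	AGC	AGG	AGT	ATA	ATC	ATG	ATT	CAA	CAC	CAG	CAT	CCA	CCC	CCG	CCT	CGA	CGC	CGG	CGT	CTA	CTC	CTG	CTT	GAA	GAC	GAG	GAT	GCA	GCC	GCG	GCT	GGA	GGC	GGG	GGT	GTA	GTC	GTG	GTT	TAA	TAC	TAG	TAT	TCA	TCC	TCG	TCT	TGA	TGC	TGG	TGT	TTA	TTC	TTG	TTT
Bendability	0.543	-0.704	1.662	-0.962	1.055	-0.637	2.703	-0.169	-0.204	0.699	2.102	1.175	-1.367	0.284	0.849	1.021	1.371	-1.09	1.117	-0.145	-0.886	1.277	-0.205	 0.64	0.507	0.348	 0.28	-1.164	0.331	-0.154	-0.313	-0.044	1.161	  0.9	0.689	-0.308	0.279	-1.991	0.455	0.274	-0.819	0.963	-0.942	1.127	-0.308	1.106	0.466	0.442	0.104	1.271	0.919	-1.438	-0.438	-1.271	0.032	-1.261	-2.102	2.316	 1.44	0.651	0.264	-0.645	0.579	-1.309
Nucleosome	 0.58	-0.36	-0.298	-0.272	0.248	0.194	0.207	-0.006	-0.023	-1.277	0.826	0.009	-0.163	-0.259	-1.357	1.605	-0.103	0.468	-0.639	0.163	-0.004	-1.338	-0.842	0.166	1.253	 0.27	-1.856	-0.845	-1.822	-1.166	-0.637	-0.663	-0.398	0.858	0.531	-0.628	    0	-0.312	2.117	-0.741	-0.567	0.927	0.601	-0.855	1.267	-0.181	-0.523	0.465	0.772	2.127	-0.563	-1.332	-0.732	-0.02	-0.465	-0.801	-0.558	-0.159	-1.112	2.196	-1.255	0.051	0.648	1.177
SYNTH-DNA-TRI-001	-0.444	-0.533	-0.318	-0.499	0.513	-1.649	-0.512	-1.335	-1.385	 1.12	0.384	0.728	-0.321	-0.01	0.417	1.476	-1.414	 1.22	-1.149	-0.981	-0.163	0.455	0.047	-0.555	-0.192	-1.482	0.209	0.811	-0.708	 2.39	0.787	-0.585	-0.055	-0.209	 0.14	-0.655	1.413	1.152	0.206	-0.95	-1.139	0.462	-0.688	0.505	 0.03	1.338	0.425	-0.356	0.321	0.154	0.724	-1.28	1.641	-0.317	0.262	-1.093	-0.111	-0.051	1.536	0.685	-0.53	-2.232	-1.118	-0.301
SYNTH-DNA-TRI-002	-0.204	0.118	0.056	 0.44	 1.87	0.515	-0.005	-0.604	0.026	-0.633	-0.524	0.643	-1.185	0.195	-0.527	-1.295	-0.289	0.308	-0.257	-0.981	-0.466	0.493	0.511	 1.37	0.628	0.555	0.795	  1.7	-1.994	-1.071	-0.33	1.046	-0.627	-0.521	-0.206	0.445	-1.462	-0.988	0.327	-1.056	-0.153	-0.293	-0.473	-1.109	0.668	-2.155	 -0.2	-0.437	 0.38	-0.898	 2.15	-1.746	0.978	-1.755	0.417	0.012	-0.174	1.434	 1.45	-1.176	0.014	0.261	-0.95	0.551
SYNTH-DNA-TRI-003	-0.347	-0.389	0.024	0.391	2.514	-0.853	1.133	0.561	-0.723	0.937	0.059	1.015	0.081	-1.686	0.438	0.894	0.201	0.933	 0.42	0.047	-3.068	-1.313	1.791	0.515	-0.789	-0.671	-2.021	0.819	-1.516	-0.427	0.052	-2.368	0.301	0.161	0.272	1.178	0.115	-0.394	-0.664	-0.606	0.563	-0.095	0.141	-1.112	-0.899	1.806	-0.521	2.022	-0.935	0.157	-0.28	-0.733	1.567	0.952	-0.306	0.754	-0.862	0.023	-0.523	0.147	-0.065	-0.134	-0.665	-0.204
SYNTH-DNA-TRI-004	-0.679	-0.177	-0.335	-0.304	0.502	-0.606	2.144	-1.29	1.268	0.662	-0.863	-0.386	1.046	-0.309	-0.554	1.184	-0.145	-0.483	-0.018	-0.57	-0.308	0.485	-1.867	0.031	-0.811	-0.262	0.634	-1.62	1.721	-1.545	1.019	-0.653	0.436	-0.968	-1.707	-0.066	 1.93	-0.673	-0.856	1.242	-0.367	-0.623	0.868	-0.405	1.247	0.836	1.247	1.322	-0.206	0.238	1.293	0.799	0.643	0.971	1.163	-0.709	0.654	-1.434	-0.838	-0.268	-1.238	 1.06	-0.268	-1.304
SYNTH-DNA-TRI-005	-0.676	1.252	 0.82	0.924	-0.766	-0.105	-0.81	0.437	-0.331	0.395	0.745	0.661	0.872	-1.099	0.984	0.923	-0.176	-0.738	0.529	0.291	2.067	-1.104	-0.982	1.537	1.285	-0.43	0.197	1.658	-1.952	0.714	-0.013	-0.159	 0.94	0.404	-0.622	-0.913	1.752	0.979	-0.397	0.983	0.983	-0.206	1.439	0.027	-0.001	1.776	-1.488	-0.39	0.992	0.625	0.145	0.861	-0.073	-1.104	-0.044	-0.192	0.397	0.558	-0.674	0.919	1.017	-1.611	 0.25	-0.37
SYNTH-DNA-TRI-006	-0.653	0.392	0.191	-0.497	-0.447	0.605	0.661	-1.113	0.695	0.112	-0.618	-0.968	-0.631	0.705	-1.565	-1.283	0.642	-0.436	-0.758	 0.13	0.093	0.789	-0.352	0.199	-0.106	-0.977	-0.592	0.391	0.035	-0.342	 1.34	-0.245	-0.88	0.046	-1.751	0.575	0.373	-0.694	  0.1	0.427	0.057	-1.328	0.362	-0.925	-1.119	0.206	0.356	0.044	-1.322	0.173	-0.802	0.402	-1.015	-1.658	-0.775	 1.33	-0.738	-0.632	-0.198	-0.747	0.195	-0.609	-1.799	-0.064
SYNTH-DNA-TRI-007	-0.025	-1.226	 1.25	0.643	-0.235	0.678	1.115	-2.388	0.518	2.517	-0.454	0.291	1.934	-1.771	-1.071	-0.112	-1.318	-0.057	 1.63	-0.065	1.058	0.326	0.192	0.676	0.023	0.934	-0.379	-0.143	0.162	1.544	0.215	-0.415	0.866	0.893	1.252	0.182	0.302	1.221	0.685	-0.924	0.697	-0.25	0.115	-1.653	0.811	-0.074	-1.482	0.086	-2.276	-0.902	0.693	0.452	0.868	-0.752	-0.876	-0.528	-0.86	1.716	0.225	1.647	-0.18	0.379	-0.325	-0.592
SYNTH-DNA-TRI-008	-1.391	1.138	-0.281	2.197	-0.903	0.042	0.971	-0.622	1.454	0.368	-0.106	0.825	-0.608	-1.399	-1.037	1.155	0.476	-2.049	2.064	-0.419	1.164	 0.35	 0.48	-0.036	-0.577	-0.684	0.958	-1.474	-1.105	0.099	-0.254	 1.03	 0.44	0.409	1.392	0.612	-1.035	-0.629	0.334	1.469	-0.507	-0.581	-1.957	0.947	0.215	1.014	1.119	0.038	-0.957	-2.418	0.303	-0.017	0.853	-0.469	-1.364	1.299	-1.616	0.497	0.463	0.333	-0.167	1.093	-0.684	0.076
SYNTH-DNA-TRI-009	-0.106	 0.89	1.514	0.813	-0.18	-1.273	0.256	-1.412	0.647	-0.555	1.436	0.878	0.712	0.323	-0.416	0.637	0.304	-0.115	1.583	-0.504	0.435	-0.271	-0.882	1.771	 1.41	 0.01	0.238	-0.685	-0.034	0.178	-1.669	-0.308	-0.099	-0.379	-0.216	 1.22	-0.799	1.186	-0.946	0.411	0.334	0.745	-0.077	-1.463	-0.492	0.162	2.134	-0.055	-0.383	0.099	-1.426	-1.237	-2.344	-0.426	0.346	0.164	0.655	-0.667	-0.354	1.845	0.611	-0.177	-1.027	-1.659
SYNTH-DNA-TRI-010	-1.015	-0.319	-0.568	-0.362	0.026	-1.018	0.484	-0.337	-2.451	0.763	1.451	0.363	-2.226	0.372	0.046	1.348	0.378	1.686	-0.795	1.583	-0.943	-1.631	0.273	0.504	0.847	0.689	1.891	1.043	1.463	-2.065	1.226	-0.431	-0.707	2.546	0.481	-0.471	0.719	0.473	0.399	1.498	-0.174	0.201	0.429	-1.776	1.202	-0.214	0.829	0.906	0.242	2.453	-1.359	-1.743	0.608	-0.775	-0.147	-1.013	0.567	-1.032	0.693	-1.284	-0.001	-0.431	-1.123	-0.509
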