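property	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
Hydrophobicity	 0.62	 0.29	 -0.9	-0.74	 1.19	 0.48	 -0.4	 1.38	 -1.5	 1.06	 0.64	-0.78	 0.12	-0.85	-2.53	-0.18	-0.05	 1.08	 0.81	 0.26
Hydrophilicity	 -0.5	   -1	    3	    3	 -2.5	    0	 -0.5	 -1.8	    3	 -1.8	 -1.3	  0.2	    0	  0.2	    3	  0.3	 -0.4	 -1.5	 -3.4	 -2.3
SideChainMass	   15	   47	   59	   73	   91	    1	   82	   57	   73	   57	   75	   58	   42	   72	  101	   31	   45	   43	  130	  107
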