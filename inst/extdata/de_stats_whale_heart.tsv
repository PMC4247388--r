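gene	transcript	logFC	p_value	p_adj	B
Asl	ENSMUST00000161094	-4.4	1.43e-05	0.015	3.19
Brk1	ENSMUST00000035725	-2.85	5.69e-06	0.00793	3.96
Eif3l	ENSMUST00000040518	-2.46	2.28e-06	0.00477	4.95
Htatip2	ENSMUST00000085272	-6	1.4e-07	0.000587	6.99
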