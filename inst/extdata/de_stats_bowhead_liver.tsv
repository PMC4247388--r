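gene	transcript	logFC	p_value	p_adj	B
Adamts13	ENSMUST00000102891	-3.84	5.55e-06	0.000895	4.06
Arap3	ENSMUST00000042944	-2.4	9.01e-07	0.000196	5.81
Atp6v1b2	ENSMUST00000006435	2.94	1.42e-08	1.34e-05	9.66
BC027231	ENSMUST00000048788	-3.12	6.29e-07	0.000161	6.15
Bgn	ENSMUST00000033741	-2.45	8e-06	0.00113	3.7
Card10	ENSMUST00000164826	-3.61	2.61e-07	8.67e-05	7
Cited2	ENSMUST00000038107	-3.08	1.14e-05	0.00137	3.37
Cxx1b	ENSMUST00000088778	-3.87	3.26e-07	9.67e-05	6.78
Cyp2r1	ENSMUST00000032908	3.42	5.8e-07	0.000156	6.21
Dtd1	ENSMUST00000028917	-2.16	6.96e-07	0.000164	6.06
Epg5	ENSMUST00000044622	-4.1	2.7e-06	0.000526	4.76
Epha2	ENSMUST00000006614	-2.76	5.78e-06	0.000898	4.03
Fam129b	ENSMUST00000028135	-2.97	3.1e-07	9.67e-05	6.83
Fam92a	ENSMUST00000108285	2.96	6.59e-07	0.000162	6.09
Fbln5	ENSMUST00000021603	-4.57	5.76e-08	4.65e-05	8.43
Grb14	ENSMUST00000028252	5.21	4.61e-09	5.2e-06	10.73
Ift122	ENSMUST00000112923	-3.02	6.41e-06	0.000952	3.93
Igj	ENSMUST00000087033	-3.3	9.15e-06	0.0012	3.59
Insig1	ENSMUST00000059155	3.04	8.94e-06	0.0012	3.63
Ints2	ENSMUST00000018212	-2.85	5.89e-06	0.000898	4.01
Iqsec1	ENSMUST00000189881	5.16	2e-07	7.52e-05	7.22
Lgals3	ENSMUST00000142734	-3.58	1.15e-07	6.48e-05	7.78
Lrrfip2	ENSMUST00000035078	2.61	2.52e-07	8.67e-05	6.99
Masp2	ENSMUST00000052060	3.46	2.63e-09	4.94e-06	11.32
Med28	ENSMUST00000156481	3.16	1.93e-06	0.000389	5.08
Nemf	ENSMUST00000021368	3.48	3.17e-06	0.000577	4.61
Ngef	ENSMUST00000068681	5.16	1.26e-07	6.48e-05	7.65
Nos3	ENSMUST00000030834	-3.58	7.94e-06	0.00113	3.72
Orc5	ENSMUST00000030872	2.69	1.92e-06	0.000389	5.09
Pdgfrb	ENSMUST00000115274	-4.44	3.62e-06	0.000638	4.48
Perp	ENSMUST00000019998	4.91	6.1e-10	3.44e-06	12.57
Pglyrp2	ENSMUST00000170392	6.23	1.25e-09	3.52e-06	11.93
Rasip1	ENSMUST00000057927	-4.69	9.75e-08	6.11e-05	7.94
Rnase4	ENSMUST00000022428	3.21	3.6e-07	0.000101	6.69
Rpa2	ENSMUST00000102561	-2.42	2.87e-06	0.000541	4.7
Rpusd4	ENSMUST00000034543	-4.13	1.84e-07	7.52e-05	7.33
Slc25a38	ENSMUST00000035106	2.9	8.36e-07	0.000189	5.87
Smad2	ENSMUST00000168423	2.12	1.58e-05	0.00181	3.09
Ssbp4	ENSMUST00000049908	-2.5	8.39e-06	0.00115	3.68
Tie1	ENSMUST00000047421	-3.79	8.04e-08	5.67e-05	8.12
Timp2	ENSMUST00000017610	-5.09	3.71e-09	5.2e-06	11.02
Top1	ENSMUST00000109468	2.18	1.07e-05	0.00135	3.45
Vac14	ENSMUST00000034190	-2.27	1.87e-07	7.52e-05	7.32
Wsb1	ENSMUST00000017821	-4.4	1.57e-07	7.4e-05	7.48
Zfp143	ENSMUST00000084727	-2.43	5.19e-06	0.000862	4.13
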