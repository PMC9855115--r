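lo	hi	ratio	x_0.50	x_0.60	x_0.63	x_0.65	x_0.70
100	125	0.2000	A	A	A	A	A
125	150	0.4000	A	A	A	A	A
150	175	0.3846	A	A	A	A	A
175	200	0.0870	A	A	A	A	A
200	225	0.2000	A	A	A	A	A
225	250	0.2113	A	A	A	A	A
250	275	0.2541	A	A	A	A	A
275	300	0.1312	A	A	A	A	A
300	325	0.0427	A	A	A	A	A
325	350	0.1233	A	A	A	A	A
350	375	0.6093	M	M	A	A	A
375	400	4.2561	N	N	N	N	N
400	425	3.3120	N	N	N	N	N
425	450	1.1848	N	N	N	N	N
450	475	0.6470	M	M	M	A	A
475	500	0.2834	A	A	A	A	A
500	525	0.1530	A	A	A	A	A
525	550	0.1506	A	A	A	A	A
550	575	0.1387	A	A	A	A	A
575	600	0.2712	A	A	A	A	A
600	625	0.1389	A	A	A	A	A
625	650	0.3571	A	A	A	A	A
650	675	0.2105	A	A	A	A	A
675	700	0.2353	A	A	A	A	A
700	725	0.1111	A	A	A	A	A
725	750	0.6667	M	M	M	M	A
750	775	0.0000	A	A	A	A	A
775	800	0.0000	A	A	A	A	A
800	825	0.0000	A	A	A	A	A
825	850	0.0000	A	A	A	A	A
850	875	0.5000	M	A	A	A	A
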