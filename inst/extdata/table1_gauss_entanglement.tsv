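pdb_id	g_prime	g_mean	n_residues	human
1M0D	-2	-1.65	129	FALSE
2J6G	-1.79	-2.08	260	FALSE
2XDP	-1.75	-2.23	123	TRUE
2Z0W	-1.67	-1.79	72	TRUE
1I1D	-1.42	-1.26	156	FALSE
2P1J	-1.34	-1.42	164	FALSE
1LGP	-1.32	-1.28	113	TRUE
1NPB	-1.3	-1.08	140	FALSE
1LOM	-1.22	-1.45	101	FALSE
2BZY	-1.19	-1.43	62	TRUE
1KLL	-1.16	-0.78	125	FALSE
1HW7	-1.13	-1.44	229	FALSE
1BYL	-1.06	-1.12	122	FALSE
1MI7	-1.05	-0.97	103	FALSE
1BUO	-1.03	-0.99	121	TRUE
1O4W	-0.95	-1.34	123	FALSE
1MU4	-0.94	-1.09	86	FALSE
1W5F	-0.92	-0.48	315	FALSE
1FRO	-0.88	-1.08	176	TRUE
2VAJ	-0.88	-0.52	93	TRUE
1HT9	-0.82	-0.87	76	FALSE
3FSV	-0.79	-0.38	119	FALSE
1ZK9	-0.78	-0.69	110	FALSE
3LOW	-0.73	-0.63	100	TRUE
1T92	-0.66	-0.61	108	FALSE
2ES0	-0.65	-0.54	131	TRUE
2RCZ	-0.53	-0.55	79	TRUE
1KAE	-0.51	-0.46	427	FALSE
1NIR	-0.51	-0.5	538	FALSE
1PUC	-0.49	-0.47	101	FALSE
1HUL	-0.49	-0.66	108	TRUE
1I4M	-0.48	-0.41	108	TRUE
2NU5	-0.43	-0.63	123	FALSE
3LYQ	-0.42	-0.74	184	FALSE
2GUD	-0.41	-0.63	122	FALSE
1R7H	-0.39	-0.57	74	FALSE
1ZXK	-0.38	-0.14	96	FALSE
1K51	-0.35	-0.47	72	FALSE
2A62	-0.35	-0.13	319	FALSE
1N9J	-0.35	-0.32	98	TRUE
1K4Z	-0.33	-0.42	157	FALSE
1TIJ	-0.33	-0.22	114	TRUE
1ZVN	-0.32	-0.13	99	FALSE
2A4E	-0.28	-0.25	208	FALSE
1DXX	-0.27	-0.17	238	TRUE
1K04	-0.27	-0.63	142	TRUE
3FJ5	-0.2	-0.23	58	FALSE
1CTS	-0.17	-0.5	437	FALSE
1FOL	-0.17	-0.35	416	FALSE
2BI4	-0.15	-0.02	382	FALSE
2ONT	-0.15	-0.09	73	TRUE
2CI8	-0.14	-0.61	106	TRUE
1DWW	-0.12	-0.29	420	FALSE
1QQ2	-0.12	-0.4	173	FALSE
1XMM	-0.1	-0.32	288	TRUE
1Q8M	-0.09	0.31	121	TRUE
1GT1	-0.08	-0.1	158	FALSE
1NNQ	-0.07	0.26	170	FALSE
3D94	-0.07	-0.04	289	TRUE
2IV0	-0.04	-0.04	412	FALSE
2W1T	-0.04	-0.07	175	FALSE
1L5X	-0.03	-0.04	270	FALSE
2E6U	-0.03	-0.02	142	FALSE
2O7M	-0.03	-0.04	153	FALSE
4AEO	-0.03	0	353	FALSE
3PSN	-0.02	-0.03	183	FALSE
1HE7	-0.02	-0.06	114	TRUE
1U4N	-0.01	0.3	308	FALSE
1UKM	-0.01	-0.01	131	FALSE
1YGT	-0.01	-0.12	104	FALSE
1XUZ	0	0.04	348	FALSE
2PA7	0	-0.04	135	FALSE
1VJ5	0	0	547	TRUE
2JFL	0	0	286	TRUE
1BJ3	0.02	0	129	FALSE
2QYP	0.02	0	78	TRUE
1X2W	0.03	0.01	129	FALSE
1QB3	0.05	0	113	FALSE
1AOJ	0.09	0.29	60	FALSE
1S8O	0.1	0.23	545	TRUE
1CDC	0.13	0.23	96	FALSE
1WY9	0.16	-0.03	111	FALSE
3NG2	0.17	0.25	66	FALSE
2HZL	0.19	0.59	338	FALSE
2FPN	0.2	2.72	198	FALSE
2CN4	0.26	0.6	173	FALSE
2SPC	0.29	0.6	107	FALSE
1R5C	0.31	0.5	124	FALSE
2CO3	0.34	0.53	142	FALSE
2OQR	0.34	0.3	227	FALSE
1H8X	0.35	0.44	125	TRUE
3HXS	0.36	-0.14	120	FALSE
1GP9	0.41	0.54	170	TRUE
2FQM	0.49	0.49	65	FALSE
2DSC	0.49	0.51	195	TRUE
1SK4	0.56	0.77	162	TRUE
2DI3	0.62	0.49	231	FALSE
2NZ7	0.63	0.55	93	TRUE
2HN1	0.66	1	246	FALSE
1OSY	0.71	1	114	FALSE
2A9U	0.76	0.86	133	TRUE
1A2W	0.78	0.83	124	FALSE
1QX7	0.81	1.08	136	FALSE
1QX5	0.83	1.09	145	FALSE
1MV8	0.86	1	436	FALSE
1QWI	0.93	1.12	140	FALSE
1WKQ	1.13	1.06	158	FALSE
1E7L	1.26	1.37	166	FALSE
3DIE	1.5	1.41	106	FALSE
1ILK	1.68	1.63	151	TRUE
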