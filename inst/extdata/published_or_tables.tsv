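table	assay	group	n_case	n_control	is_reference	or_printed	ci_lo_printed	ci_hi_printed	p_printed	mi_affected
1a	qPCR	0-2	444	446	TRUE	1.00				FALSE
1a	qPCR	1-1	229	207	FALSE	1.11	0.88	1.40	0.3673	FALSE
1a	qPCR	2-0	26	28	FALSE	0.92	0.52	1.61	0.7713	TRUE
1a	qPCR	2-1	15	16	FALSE	0.94	0.46	1.93	0.8695	FALSE
1a	qPCR	1-2	13	14	FALSE	0.93	0.43	2.01	0.8587	FALSE
1a	qPCR	0-1	13	11	FALSE	1.19	0.53	2.68	0.6794	FALSE
1a	qPCR	1-0	4	3	FALSE	1.34	0.30	6.02	0.7031	FALSE
1a	qPCR	3-0	3	2	FALSE	1.52	0.27	8.62	0.6369	TRUE
1a	SNP	0-2	4094	3222	TRUE	1				FALSE
1a	SNP	1-1	2050	1628	FALSE	0.99	0.92	1.07	0.8349	FALSE
1a	SNP	2-0	229	225	FALSE	0.79	0.65	0.96	0.0193	TRUE
1a	SNP	2-1	121	101	FALSE	0.92	0.7	1.2	0.5246	TRUE
1a	SNP	1-2	98	74	FALSE	1.04	0.77	1.42	0.7822	TRUE
1a	SNP	0-1	116	77	FALSE	1.19	0.89	1.59	0.2535	FALSE
1a	SNP	1-0	25	21	FALSE	0.94	0.52	1.68	0.8255	FALSE
1a	SNP	3-0	11	14	FALSE	0.74	0.3	1.82	0.518	TRUE
1b	qPCR	2	457	460	TRUE	1.00				FALSE
1b	qPCR	1	257	234	FALSE	1.11	0.89	1.38	0.3702	FALSE
1b	qPCR	0	33	33	FALSE	1.01	0.61	1.66	0.9795	FALSE
1b	SNP	2	4192	3296	TRUE	1				FALSE
1b	SNP	1	2287	1806	FALSE	0.99	0.92	1.07	0.8883	TRUE
1b	SNP	0	265	260	FALSE	0.8	0.67	0.96	0.0151	FALSE
1c	qPCR	0	457	457	TRUE	1.00				FALSE
1c	qPCR	1	246	224	FALSE	1.10	0.88	1.37	0.4096	FALSE
1c	qPCR	2	41	44	FALSE	0.94	0.60	1.47	0.7787	TRUE
1c	qPCR	3	3	2	FALSE	1.24	0.21	7.28	0.8084	TRUE
1c	SNP	0	4210	3299	TRUE	1				FALSE
1c	SNP	1	2173	1723	FALSE	0.99	0.91	1.07	0.7785	FALSE
1c	SNP	2	350	326	FALSE	0.83	0.71	0.97	0.0212	TRUE
1c	SNP	3	11	14	FALSE	0.74	0.3	1.82	0.5119	TRUE
2a	qPCR	0-2	259	286	TRUE	1.00				FALSE
2a	qPCR	1-1	123	128	FALSE	1.06	0.79	1.43	0.6976	FALSE
2a	qPCR	2-0	16	15	FALSE	1.22	0.58	2.57	0.5985	TRUE
2a	qPCR	2-1	7	13	FALSE	0.59	0.23	1.51	0.2754	FALSE
2a	qPCR	1-2	8	8	FALSE	1.10	0.41	2.98	0.8450	FALSE
2a	qPCR	0-1	10	7	FALSE	1.58	0.59	4.20	0.3621	FALSE
2a	qPCR	1-0	2	1	FALSE	2.21	0.20	24.50	0.5187	FALSE
2a	qPCR	3-0	3	0	FALSE					FALSE
2a	SNP	0-2	1027	1157	TRUE	1				FALSE
2a	SNP	1-1	555	582	FALSE	1.08	0.93	1.24	0.3119	TRUE
2a	SNP	2-0	59	88	FALSE	0.76	0.54	1.07	0.1133	TRUE
2a	SNP	2-1	34	40	FALSE	0.93	0.58	1.48	0.7529	TRUE
2a	SNP	1-2	24	33	FALSE	0.85	0.5	1.45	0.5502	TRUE
2a	SNP	0-1	36	24	FALSE	1.69	1	2.85	0.0491	FALSE
2a	SNP	1-0	7	4	FALSE	1.97	0.58	6.76	0.2793	TRUE
2a	SNP	3-0	5	0	FALSE					FALSE
2b	qPCR	2	267	294	TRUE	1.00				FALSE
2b	qPCR	1	140	148	FALSE	1.04	0.78	1.38	0.7787	FALSE
2b	qPCR	0	21	16	FALSE	1.45	0.74	2.83	0.2822	FALSE
2b	SNP	2	1051	1190	TRUE	1				FALSE
2b	SNP	1	625	646	FALSE	1.09	0.95	1.26	0.1975	TRUE
2b	SNP	0	71	92	FALSE	0.88	0.64	1.21	0.4181	TRUE
2c	qPCR	0	159	187	TRUE	1.00				FALSE
2c	qPCR	1	93	83	FALSE	1.32	0.92	1.90	0.1370	FALSE
2c	qPCR	2	12	14	FALSE	1.01	0.45	2.24	0.9842	FALSE
2c	qPCR	3	2	0	FALSE					FALSE
2c	SNP	0	649	733	TRUE	1				FALSE
2c	SNP	1	383	366	FALSE	1.18	0.99	1.41	0.0628	FALSE
2c	SNP	2	61	75	FALSE	0.91	0.64	1.3	0.607	TRUE
2c	SNP	3	3	0	FALSE					FALSE
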