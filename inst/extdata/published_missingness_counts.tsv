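chrom	n_mapped	miss_SubL1	pct_SubL1	miss_SubL2	pct_SubL2	miss_SubL3	pct_SubL3
1A	2632	35	1.3	28	1.1	26	1.0
1B	2630	27	1.0	36	1.4	27	1.0
1D	2495	19	0.8	24	1.0	21	0.8
2A	2622	14	0.5	18	0.7	20	0.8
2B	2578	33	1.3	31	1.2	45	1.7
2D	2590	204	7.9	207	8.0	205	7.9
3A	2194	31	1.4	24	1.1	32	1.5
3B	2629	32	1.2	34	1.3	46	1.7
3D	2072	17	0.8	21	1.0	23	1.1
4A	2573	34	1.3	35	1.4	41	1.6
4B	2601	1535	59.0	1560	60.0	1575	60.6
4D	1087	28	2.6	36	3.3	30	2.8
5A	2633	37	1.4	53	2.0	44	1.7
5B	2622	39	1.5	50	1.9	64	2.4
5D	2142	33	1.5	40	1.9	48	2.2
6A	2623	40	1.5	49	1.9	40	1.5
6B	2601	94	3.6	107	4.1	91	3.5
6D	2067	30	1.5	30	1.5	24	1.2
7A	2601	28	1.1	42	1.6	41	1.6
7B	2542	212	8.3	219	8.6	198	7.8
7D	2625	23	0.9	23	0.9	23	0.9
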