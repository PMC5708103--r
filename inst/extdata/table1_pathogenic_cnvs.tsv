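no	sample_id	group	sex	chrom	cytoband	start_1based	size_bp	state	segdup	genes_n	karyotype_level
1	2	average	M	1	1q21.1	145760806	2083985	gain	1	17	0
2	3	average	F	1	1q21.1	145932468	1898716	gain	1	15	0
3	562	ID	F	2	2p16.3	51066869	563162	loss	0	1	0
4	570	borderline	M	2	2p16.3	51181653	189279	loss	0	1	0
5	7	average	M	2	2q13	111388632	1727361	gain	1	9	0
6	8	average	M	2	2q13	111388632	1727361	loss	1	9	0
7	9	NVLD	M	2	2q13	111388632	1727361	gain	1	9	0
8	396	NVLD	M	3	3p26.1	4418429	277309	loss	0	3	0
9	13	NVLD	M	3	3q13.31	113825760	2062410	loss	0	6	0
10	452	ID	M	3	3q27.1-q27.2	184400855	1580956	loss	0	17	0
11	565	borderline	F	5	5p15.33-5p15.2	113577	10191390	loss	0	83	0
12	17	average	F	5	5p15.33-p15.32	1811574	3687431	loss	0	7	0
13	247	ID	F	6	6p25.3-p25.1	149661	6836705	loss	0	35	0
14	565	borderline	F	6	6q26-q27	163617482	7302001	gain	0	59	0
15	206	borderline	F	7	7q22.2-q31.1	105517719	10037597	loss	0	34	0
16	115	borderline	F	8	8p23.3-p23.1	158062	6830865	loss	1	21	0
17	40	average	M	10	10q11.22-q11.23	46485761	5173684	gain	1	42	0
18	569	ID	M	13	13q14.13-q14.3	46589256	6220619	loss	0	59	0
19	48	borderline	M	15	15q11.2-q13.1	20181700	6498447	gain	1	121	0
20	556	ID	M	15	15q11.2-q13.1	22770422	5757338	gain	1	116	0
21	427	NVLD	F	15	15q11.2-q13.1	23290799	5353780	gain	1	115	0
22	49	NVLD	M	15	15q11.2-q13.1	23641514	5432624	gain	1	106	0
23	50	average	M	15	15q11.2-q13.1	23641514	4892894	gain	1	101	0
24	52	ID	F	15	15q13.2-q13.3	30821637	1690584	loss	1	8	0
25	568	borderline	M	16	16p11.2	29432213	744308	loss	1	40	0
26	55	ID	F	16	16p11.2	29567309	624599	gain	1	26	0
27	56	ID	F	16	16p11.2	29567309	659635	gain	1	33	0
28	57	ID	M	16	16p11.2	29567309	624599	gain	1	26	0
29	58	ID	M	16	16p11.2	29567309	659635	gain	1	33	0
30	277	ID	F	19	19p13.3-p13.2	2754548	9685341	gain	0	280	0
31	577	borderline	M	22	22q11.21	18890046	2831545	loss	1	46	0
32	581	ID	F	22	22q11.21	18890046	2831545	loss	1	46	0
33	582	ID	M	22	22q11.21	18890046	2831545	loss	1	46	0
34	579	borderline	M	22	22q11.21	18895226	2466420	loss	1	46	0
35	580	NVLD	F	22	22q11.21	18916840	1395833	loss	1	29	0
36	578	ID	F	22	22q11.2	20717655	1087074	loss	1	16	0
37	271	average	F	X	whole-X	1	155065370	loss	0	829	1
38	173	borderline	M	X	whole-X	1	155065370	gain	0	829	1
39	57	ID	M	X	whole-X	1	155065370	gain	0	829	1
40	194	average	M	X	Xp22.33-p22.2	2400835	11075950	loss	0	40	0
41	574	ID	F	X	Xp11.23-p11.22	48178414	4508892	gain	1	97	0
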