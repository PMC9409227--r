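region_no	merged_region_id	chrom	start	end	length	genes	upregulated	positions
1	3	chr1	3453352	3483697	30345	PRDM16;ARHGEF16	0;0	downstream;in gene
2	35	chr1	31689438	31715640	26202	COL16A1;LOC101929444;BAI(ADGRB2)	1;0;1	in gene;downstream;downstream
3	52	chr1	46170382	46203757	33375	PIK3R3;LOC105378695;TSPAN1;POMGNT1;LURAP1	0;0;0;1;0	upstream;upstream;in gene;downstream;upstream
4	89	chr1	151536650	151553908	17258	CGN;TUFT1;MIR554	0;0;0	downstream;in gene;upstream
5	121	chr1	180501359	180533622	32263	ACBD6	1	upstream
6	131	chr1	200885778	200903119	17341	GPR25;C1orf106;MROH3P	0;1;0	downstream;in gene;upstream
7	135	chr1	202566931	202600283	33352	PPP1R12B;SYT2;LOC105371686;LOC105371685	0;0;0;0	in gene;downstream;upstream;upstream
8	166	chr1	240758392	240811761	53369	LOC100506929;RGS7;LOC105373229	0;0;0	upstream;in gene;upstream
9	208	chr10	72243611	72278769	35158	ANAPC16	0	downstream
10	212	chr10	75207300	75264014	56714	VDAC2;COMTD1	0;0	downstream;in gene
11	248	chr10	132395732	132422986	27254	LRRC27;PWWP2B;LOC105378568;C10orf91	0;0;0;1	downstream;in gene;downstream;upstream
12	254	chr11	8806999	8841147	34148	ST5;LOC102724784;RNA5SP330	0;0;0	in gene;downstream;upstream
13	259	chr11	12788054	12842696	54642	TEAD1	0	in gene
14	284	chr11	63559618	63584348	24730	RARRES3;HRASLS2;PLA2G16;LOC105369335	0;1;0;0	downstream;upstream;downstream;upstream
15	289	chr11	65371027	65392675	21648	TIGD3;SLC25A45	1;0	downstream;in gene
16	315	chr11	114280212	114309047	28835	NNMT	0	upstream
17	390	chr12	47811914	47836614	24700	LOC105369749	0	upstream
18	429	chr12	79545485	79567438	21953	PAWR	0	downstream
19	460	chr12	122696516	122727563	31047	HCAR2;HCAR3;HCAR1	0;0;0	upstream;downstream;downstream
20	471	chr13	33118131	33129383	11252	STARD13	1	in gene
21	482	chr13	79480690	79494906	14216	NDFIP2-AS1;NDFIP2	0;0	upstream;in gene
22	502	chr14	22588162	22622517	34355	DAD1;ABHD4	0;0	upstream;in gene
23	585	chr15	73973341	73997593	24252	STOML1;PML	0;1	in gene;upstream
24	633	chr16	68731540	68802326	70786	CDH1	0	downstream
25	641	chr16	81559343	81602113	42770	MIR6504	0	in gene;upstream
26	672	chr17	17900207	17972359	72152	TOM1L2;LRRC48;ATPAF2	0;0;0	in gene;upstream;downstream
27	674	chr17	19706613	19729962	23349	SLC47A2;ALDH3A1	1;0	in gene;downstream
28	699	chr17	42658915	42683176	24261	HMGB3P27;TUBG2;PLEKHH3;CCR10;CNTNAP1;EZH1;MIR6780A	0;1;0;0;1;0;0	downstream;downstream;in gene;downstream;upstream;downstream;downstream
29	746	chr17	82096030	82108208	12178	FASN	0	upstream
30	764	chr18	57770620	57846982	76362	ATP8B1;LOC1 + G3305376870;RSL24D1P11	0;0;0	upstream;downstream;upstream
31	775	chr19	2523762	2555593	31831	LOC101929097;GNG7	0;0	upstream;in gene
32	776	chr19	4367944	4403867	35923	MPND;SH3GL1;CHAF1A	0;0;1	downstream;in gene;upstream
33	778	chr19	6719422	6747512	28090	C3;GPR108;MIR6791;TRIP10;SH2D3A	0;0;0;0;1	upstream;in gene;downstream;upstream;downstream
34	790	chr19	18361769	18388017	26248	PGPEP1;GDF15;MIR3189;LRRC25	0;0;0;0	downstream;upstream;upstream;downstream
35	797	chr19	38251595	38320090	68495	PPP1R14A;SPINT2;YIF1B;C19orf33;KCNK6	0;0;1;0;0	upstream;in gene;downstream;upstream;upstream
36	811	chr19	43104469	43131735	27266	PSG5;PSG2	1;1	in gene;upstream
37	817	chr19	46191369	46232922	41553	IGFL2;LOC105372424;LOC645553;LOC105372423;LOC105372422;IGFL1	1;0;0;0;0;0	downstream;upstream;in gene;downstream;downstream;upstream
38	840	chr2	26755019	26773104	18085	C2orf18(SLC35F6);CENPA	1;1	upstream;upstream
39	849	chr2	36476174	36505315	29141	CRIM	0	in gene
40	905	chr2	85237328	85298810	61482	TCF7L1;LOC102724579;LOC105374839	0;0;0	in gene;downstream;downstream
41	995	chr20	10653952	10675733	21781	JAG1;MIR6870;LOC105372526	1;0;0	in gene;upstream;upstream
42	998	chr20	19903485	19958418	54933	RIN2	0	in gene
43	1081	chr21	38898236	38926384	28148	LOC400867	0	in gene
44	1084	chr21	41751747	41787733	35986	RIPK4;MIR6814;LOC102724800;PRDM15	0;0;0;0	upstream;upstream;in gene;downstream
45	1101	chr22	24950104	24997098	46994	TMEM211;KIAA1671	0;0	upstream;in gene
46	1111	chr22	31629899	31663559	33660	SFI1;PISD;MIR7109;PRR14L	0;1;0;0	downstream;in gene;upstream;downstream
47	1121	chr22	37887250	37908095	20845	EIF3L;MICALL1	0;1	downstream;upstream
48	1127	chr22	40482368	40542411	60043	MKL1;LOC101927257;LOC105373037	1;0;0	in gene;upstream;upstream
49	1135	chr22	46731873	46775788	43915	CERK;LOC105373077;TBC1D22A	0;0;0	upstream;upstream;upstream
50	1155	chr3	37934276	37947923	13647	CTDSPL;MIR26A1	0;0	in gene;upstream
51	1189	chr3	123583773	123653831	70058	HACD2;MYLK-AS1	0;0	upstream;in gene
52	1207	chr3	153130215	153165195	34980	RAP2B	1	upstream
53	1223	chr3	183253290	183297852	44562	MCF2L2;B3GNT5;RNA5SP151	0;1;0	in gene;downstream;upstream
54	1237	chr3	197482394	197521067	38673	LOC105374308;LOC105374309;BDH1	0;0;0	upstream;downstream;downstream
55	1299	chr5	57681786	57700891	19105	LOC101928505	0	downstream
56	1392	chr6	33731250	33789203	57953	C6orf125(UQCC2);IP6K3;LEMD2;LOC105375024;MLN	1;0;1;0;0	upstream;upstream;downstream;upstream;downstream
57	1473	chr7	27080276	27115997	35721	HOXA1;HOTAIRM1;HOXA2;LOC105375205	1;0;0;0	upstream;in gene;downstream;upstream
58	1475	chr7	28034605	28067086	32481	JAZF1;LOC105375208	0;0	in gene;in gene
59	1496	chr7	47633320	47694065	60745	LINC01447;C7orf65	0;1	downstream;downstream
60	1555	chr8	22561116	22605497	44381	PPP3CC;SORBS3;LOC105379320;PDLIM2;C8orf58;CCAR2;BIN3	0;0;0;0;1;0;0	downstream;downstream;upstream;in gene;upstream;upstream;downstream
61	1634	chr8	140722495	140734727	12232	MIR151A	0	downstream
62	1640	chr8	142777613	142796025	18412	LYNX1;LY6D	0;0	upstream;upstream
63	1655	chr9	22079706	22119693	39987	CDKN2B-AS1	0	in gene
64	1672	chr9	93093990	93149539	55549	SUSD3;LOC101927993;C9orf89;NINJ1;LOC105376150	0;0;1;0;0	downstream;upstream;downstream;in gene;upstream
65	1677	chr9	106860435	106921639	61204	LOC105376204;ZNF462	0;0	upstream;in gene
66	1703	chr9	129314856	129336831	21975	C9orf106;LINC01503	0;0	downstream;upstream
67	1708	chr9	136533550	136579457	45907	NOTCH1;MIR4673;LOC1053763204;MIR4674;LINC01573	0;0;0;0;0	upstream;upstream;downstream;upstream;downstream
68	1709	chr9	136881365	136905108	23743	MAMDC4;EDF1;LOC105376326;TRAF2;MIR4479	0;0;0;1;0	downstream;upstream;upstream;in gene;downstream
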