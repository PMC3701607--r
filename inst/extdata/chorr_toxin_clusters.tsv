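rank	cluster	cluster_size	length	pct_total	pct_toxin
1	SVSP-1a	2	3346	6.762	16.534
2	SVSP-3a	2	1915	6.272	15.337
3	BPP-1a	2	1484	5.120	12.519
4	SVSP-10	1	2512	4.131	10.101
5	PLA2-2	1	880	3.346	8.183
6	SVSP-2a	2	2089	3.305	8.082
7	PLA2-1a	2	933	2.884	7.051
8	PLA2-3	1	832	1.349	3.298
9	SVSP-7	1	2209	0.900	2.200
10	SVSP-4a	2	2354	0.827	2.021
11	VEGF-1	1	1352	0.797	1.948
12	PLA2-4	1	1303	0.687	1.681
13	PLA2-6	1	880	0.542	1.325
14	PLA2-9	1	812	0.502	1.228
15	SVSP-5	1	2968	0.466	1.140
16	LAAO	1	2890	0.452	1.106
17	SVSP-8	1	1718	0.438	1.071
18	SVSP-11	1	2704	0.384	0.940
19	CRISP	1	6054	0.317	0.775
20	VESP	1	1587	0.262	0.640
21	SVSP-9	1	1341	0.189	0.461
22	SVSP-6	1	1794	0.140	0.342
23	NGF	1	1074	0.114	0.280
24	NUC	1	2538	0.114	0.278
25	PDE	1	2790	0.106	0.260
26	NF	1	1230	0.088	0.215
27	MYO	1	415	0.080	0.195
28	VEGF-2	1	5612	0.044	0.107
29	SVMPIII-1	1	3395	0.040	0.099
30	KUN-1	1	2246	0.040	0.099
31	HYAL	1	3477	0.038	0.093
32	CTL-10	1	633	0.029	0.070
33	CREGF	1	1625	0.028	0.069
34	GC	1	6138	0.021	0.051
35	CTL-11	1	575	0.019	0.046
36	CTL-2a	2	669	0.011	0.027
37	KUN-2	1	4317	0.008	0.020
38	CTL-1a	2	815	0.006	0.015
39	CTL-3	1	735	0.006	0.015
40	CTL-8	1	808	0.006	0.015
41	CTL-7	1	644	0.005	0.012
42	SVMPI	1	1677	0.004	0.009
43	PDE-6	1	4011	0.004	0.009
44	PDE-4	1	3553	0.003	0.006
45	VF	1	5139	0.002	0.005
46	CTL-4	1	697	0.002	0.004
47	CTL-5	1	743	0.002	0.004
48	PLA2-5	1	612	0.001	0.003
49	CTL-9	1	803	0.001	0.003
50	SVMPIII-2	1	2499	0.001	0.003
51	CTL-6	1	637	0.001	0.002
52	PLA2-8	1	547	0.001	0.002
53	PLA2-7	1	546	0.001	0.001
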