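rank	haplotype	n_homozygotes	observed_frequency	expected_frequency
1	A*03~B*35	195	0.00940	0.009106
2	A*03~B*07	135	0.00651	0.005687
3	A*02~B*15	107	0.00516	0.005127
4	A*01~B*08	62	0.00299	0.003129
5	A*02~B*27	54	0.00260	0.002584
6	A*02~B*44	26	0.00125	0.000954
7	A*02~B*07	22	0.00106	0.001288
8	A*02~B*40	22	0.00106	0.001146
9	A*03~B*15	22	0.00106	0.000803
10	A*02~B*51	12	0.00058	0.000507
11	A*24~B*40	11	0.00053	0.000526
12	A*02~B*13	7	0.00034	0.000595
13	A*24~B*39	6	0.00029	0.000217
14	A*02~B*56	5	0.00024	0.000180
15	A*24~B*07	5	0.00024	0.000161
16	A*31~B*18	3	0.00014	0.000166
17	A*03~B*18	3	0.00014	0.000149
18	A*02~B*08	3	0.00014	0.000097
19	A*11~B*35	2	0.00010	0.000112
20	A*11~B*44	2	0.00010	0.000091
21	A*68~B*51	2	0.00010	0.000058
22	A*31~B*51	2	0.00010	0.000043
23	A*32~B*40	2	0.00010	0.000043
24	A*68~B*35	2	0.00010	0.000036
25	A*68~B*44	2	0.00010	0.000038
26	A*26~B*40	2	0.00010	0.000021
27	A*69~B*08	2	0.00010	0.000082
28	A*02~B*35	1	0.00005	0.000191
29	A*24~B*15	1	0.00005	0.000122
30	A*02~B*18	1	0.00005	0.000107
31	A*24~B*35	1	0.00005	0.000104
32	A*25~B*18	1	0.00005	0.000081
33	A*03~B*27	1	0.00005	0.000086
34	A*03~B*44	1	0.00005	0.000056
35	A*32~B*44	1	0.00005	0.000044
36	A*03~B*40	1	0.00005	0.000047
37	A*03~B*51	1	0.00005	0.000042
38	A*31~B*40	1	0.00005	0.000020
39	A*31~B*39	1	0.00005	0.000014
40	A*11~B*55	1	0.00005	0.000008
41	A*01~B*07	1	0.00005	0.000009
42	A*29~B*44	1	0.00005	0.000007
43	A*32~B*35	1	0.00005	0.000007
44	A*23~B*44	1	0.00005	0.000007
45	A*01~B*39	1	0.00005	0.000004
46	A*01~B*51	1	0.00005	0.000006
47	A*24~B*51	1	0.00005	0.000007
48	A*68~B*15	1	0.00005	0.000005
49	A*24~B*08	1	0.00005	0.000002
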