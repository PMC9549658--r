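rank	haplotype	n_homozygotes	observed_frequency	expected_frequency	het_pct	fer	confirmed
1	A*03:01~B*35:01~C*04:01~DRB1*01:01~DQA1*01:01~DQB1*05:01	149	0.00718522	0.00690815	0.12	FALSE	FALSE
2	A*01:01~B*08:01~C*07:01~DRB1*03:01~DQA1*05:01~DQB1*02:01	48	0.00231470	0.00242061	0.41	FALSE	FALSE
3	A*03:01~B*07:02~C*07:02~DRB1*15:01~DQA1*01:02~DQB1*06:02	27	0.00130202	0.00113331	0.64	FALSE	FALSE
4	A*02:01~B*07:02~C*07:02~DRB1*15:01~DQA1*01:02~DQB1*06:02	7	0.00033756	0.00051551	2.11	FALSE	TRUE
5	A*02:01~B*13:02~C*06:02~DRB1*07:01~DQA1*02:01~DQB1*02:02	7	0.00033756	0.00039721	0.67	FALSE	TRUE
6	A*02:01~B*15:01~C*03:04~DRB1*04:01~DQA1*03:01~DQB1*03:02	7	0.00033756	0.00029789	1.23	FALSE	TRUE
7	A*03:01~B*07:02~C*07:02~DRB1*13:01~DQA1*01:03~DQB1*06:03	6	0.00028934	0.00035215	1.62	FALSE	FALSE
8	A*02:01~B*27:05~C*02:02~DRB1*08:01~DQA1*04:01~DQB1*04:02	5	0.00024111	0.00031656	0.01	FALSE	FALSE
9	A*02:01~B*51:01~C*15:02~DRB1*09:01~DQA1*03:02~DQB1*03:03	5	0.00024111	0.00013848	0.02	TRUE	TRUE
10	A*03:01~B*15:01~C*03:03~DRB1*08:01~DQA1*04:01~DQB1*04:02	5	0.00024111	0.00007897	0.02	TRUE	FALSE
11	A*02:01~B*15:01~C*03:03~DRB1*13:01~DQA1*01:03~DQB1*06:03	4	0.00019289	0.00017316	2.31	FALSE	FALSE
12	A*24:02~B*40:01~C*03:04~DRB1*13:02~DQA1*01:02~DQB1*06:04	4	0.00019289	0.00011964	0.12	FALSE	FALSE
13	A*02:01~B*27:05~C*01:02~DRB1*01:01~DQA1*01:01~DQB1*05:01	4	0.00019289	0.00011769	1.16	FALSE	FALSE
14	A*02:01~B*15:01~C*04:01~DRB1*08:01~DQA1*04:01~DQB1*04:02	3	0.00014467	0.00018545	0.09	FALSE	FALSE
15	A*03:01~B*18:01~C*07:01~DRB1*04:04~DQA1*03:01~DQB1*03:02	3	0.00014467	0.00007943	0.02	TRUE	TRUE
16	A*02:01~B*08:01~C*07:01~DRB1*03:01~DQA1*05:01~DQB1*02:01	3	0.00014467	0.00006399	2.21	FALSE	FALSE
17	A*31:01~B*18:01~C*07:01~DRB1*15:01~DQA1*01:02~DQB1*06:02	2	0.00009645	0.00013433	0.03	TRUE	FALSE
18	A*03:01~B*07:02~C*03:04~DRB1*01:01~DQA1*01:01~DQB1*05:01	2	0.00009645	0.00008789	2.43	TRUE	FALSE
19	A*02:01~B*40:01~C*03:04~DRB1*13:02~DQA1*01:02~DQB1*06:04	2	0.00009645	0.00007268	2.35	FALSE	FALSE
20	A*24:02~B*39:01~C*07:02~DRB1*08:01~DQA1*04:01~DQB1*04:02	2	0.00009645	0.00002717	2.90	TRUE	FALSE
21	A*02:01~B*15:01~C*04:01~DRB1*15:01~DQA1*01:02~DQB1*06:02	2	0.00009645	0.00000850	0.40	TRUE	FALSE
22	A*02:01~B*44:02~C*05:01~DRB1*12:01~DQA1*05:05~DQB1*03:01	1	0.00004822	0.00007523	5.20	FALSE	FALSE
23	A*68:01~B*08:01~C*07:01~DRB1*03:01~DQA1*05:01~DQB1*02:01	1	0.00004822	0.00006170	0.00	FALSE	FALSE
24	A*02:01~B*27:05~C*01:02~DRB1*04:08~DQA1*03:03~DQB1*03:01	1	0.00004822	0.00003359	0.03	TRUE	FALSE
25	A*24:02~B*35:01~C*04:01~DRB1*01:01~DQA1*01:01~DQB1*05:01	1	0.00004822	0.00002598	0.02	FALSE	FALSE
26	A*02:01~B*56:01~C*01:02~DRB1*04:01~DQA1*03:01~DQB1*03:02	1	0.00004822	0.00002582	0.01	TRUE	FALSE
27	A*03:01~B*15:01~C*03:04~DRB1*04:01~DQA1*03:01~DQB1*03:02	1	0.00004822	0.00002199	0.06	FALSE	FALSE
28	A*31:01~B*51:01~C*01:02~DRB1*13:01~DQA1*03:02~DQB1*03:03	1	0.00004822	0.00002156	0.40	TRUE	TRUE
29	A*02:01~B*56:01~C*01:02~DRB1*15:01~DQA1*01:02~DQB1*06:02	1	0.00004822	0.00001116	0.03	TRUE	FALSE
30	A*02:01~B*27:05~C*02:02~DRB1*01:01~DQA1*01:01~DQB1*05:01	1	0.00004822	0.00000611	6.73	FALSE	FALSE
31	A*29:02~B*44:03~C*16:01~DRB1*07:01~DQA1*02:01~DQB1*02:02	1	0.00004822	0.00000374	0.08	FALSE	FALSE
32	A*23:01~B*44:03~C*04:01~DRB1*07:01~DQA1*02:01~DQB1*02:02	1	0.00004822	0.00000318	0.25	FALSE	FALSE
33	A*32:01~B*40:02~C*03:04~DRB1*14:02~DQA1*05:03~DQB1*03:01	1	0.00004822	0.00000300	0.14	FALSE	FALSE
34	A*03:01~B*15:01~C*03:03~DRB1*13:02~DQA1*01:02~DQB1*06:04	1	0.00004822	0.00000290	0.01	FALSE	FALSE
35	A*32:01~B*35:01~C*04:01~DRB1*04:01~DQA1*03~DQB1*03:01	1	0.00004822	0.00000218	0.07	FALSE	FALSE
36	A*11:01~B*44:02~C*05:01~DRB1*04:04~DQA1*03:01~DQB1*03:02	1	0.00004822	0.00000146	0.03	FALSE	FALSE
37	A*32:01~B*44:02~C*05:01~DRB1*15:01~DQA1*01:02~DQB1*06:02	1	0.00004822	0.00000127	0.06	FALSE	FALSE
38	A*11:01~B*35:01~C*03:03~DRB1*08:01~DQA1*04:01~DQB1*04:02	1	0.00004822	0.00000048	0.06	FALSE	FALSE
39	A*25:01~B*08:01~C*07:01~DRB1*03:01~DQA1*05:01~DQB1*02:01	1	0.00004822	0.00000008	0.08	FALSE	FALSE
40	A*26:01~B*40:02~C*03:04~DRB1*08:01~DQA1*04:01~DQB1*04:02	1	0.00004822	0.00000004	0.12	FALSE	FALSE
41	A*02:01~B*51:01~C*15:02~DRB1*04:01~DQA1*03:01~DQB1*03:02	1	0.00004822	0.00000001	0.03	FALSE	FALSE
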