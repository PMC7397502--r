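index	label
1	AC>CA
2	AC>CG
3	AC>CT
4	AC>GA
5	AC>GG
6	AC>GT
7	AC>TA
8	AC>TG
9	AC>TT
10	AT>CA
11	AT>CC
12	AT>CG
13	AT>GA
14	AT>GC
15	AT>TA
16	CC>AA
17	CC>AG
18	CC>AT
19	CC>GA
20	CC>GG
21	CC>GT
22	CC>TA
23	CC>TG
24	CC>TT
25	CG>AT
26	CG>GC
27	CG>GT
28	CG>TA
29	CG>TC
30	CG>TT
31	CT>AA
32	CT>AC
33	CT>AG
34	CT>GA
35	CT>GC
36	CT>GG
37	CT>TA
38	CT>TC
39	CT>TG
40	GC>AA
41	GC>AG
42	GC>AT
43	GC>CA
44	GC>CG
45	GC>TA
46	TA>AT
47	TA>CG
48	TA>CT
49	TA>GC
50	TA>GG
51	TA>GT
52	TC>AA
53	TC>AG
54	TC>AT
55	TC>CA
56	TC>CG
57	TC>CT
58	TC>GA
59	TC>GG
60	TC>GT
61	TG>AA
62	TG>AC
63	TG>AT
64	TG>CA
65	TG>CC
66	TG>CT
67	TG>GA
68	TG>GC
69	TG>GT
70	TT>AA
71	TT>AC
72	TT>AG
73	TT>CA
74	TT>CC
75	TT>CG
76	TT>GA
77	TT>GC
78	TT>GG
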