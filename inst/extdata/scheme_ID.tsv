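index	label
1	DEL.C.1.1
2	DEL.C.1.2
3	DEL.C.1.3
4	DEL.C.1.4
5	DEL.C.1.5
6	DEL.C.1.6+
7	DEL.T.1.1
8	DEL.T.1.2
9	DEL.T.1.3
10	DEL.T.1.4
11	DEL.T.1.5
12	DEL.T.1.6+
13	INS.C.1.0
14	INS.C.1.1
15	INS.C.1.2
16	INS.C.1.3
17	INS.C.1.4
18	INS.C.1.5+
19	INS.T.1.0
20	INS.T.1.1
21	INS.T.1.2
22	INS.T.1.3
23	INS.T.1.4
24	INS.T.1.5+
25	DEL.R.2.1
26	DEL.R.2.2
27	DEL.R.2.3
28	DEL.R.2.4
29	DEL.R.2.5
30	DEL.R.2.6+
31	DEL.R.3.1
32	DEL.R.3.2
33	DEL.R.3.3
34	DEL.R.3.4
35	DEL.R.3.5
36	DEL.R.3.6+
37	DEL.R.4.1
38	DEL.R.4.2
39	DEL.R.4.3
40	DEL.R.4.4
41	DEL.R.4.5
42	DEL.R.4.6+
43	DEL.R.5+.1
44	DEL.R.5+.2
45	DEL.R.5+.3
46	DEL.R.5+.4
47	DEL.R.5+.5
48	DEL.R.5+.6+
49	INS.R.2.0
50	INS.R.2.1
51	INS.R.2.2
52	INS.R.2.3
53	INS.R.2.4
54	INS.R.2.5+
55	INS.R.3.0
56	INS.R.3.1
57	INS.R.3.2
58	INS.R.3.3
59	INS.R.3.4
60	INS.R.3.5+
61	INS.R.4.0
62	INS.R.4.1
63	INS.R.4.2
64	INS.R.4.3
65	INS.R.4.4
66	INS.R.4.5+
67	INS.R.5+.0
68	INS.R.5+.1
69	INS.R.5+.2
70	INS.R.5+.3
71	INS.R.5+.4
72	INS.R.5+.5+
73	DEL.MH.2.1
74	DEL.MH.3.1
75	DEL.MH.3.2
76	DEL.MH.4.1
77	DEL.MH.4.2
78	DEL.MH.4.3
79	DEL.MH.5+.1
80	DEL.MH.5+.2
81	DEL.MH.5+.3
82	DEL.MH.5+.4
83	DEL.MH.5+.5+
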