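index	label
1	A[C>A]A
2	A[C>A]C
3	A[C>A]G
4	A[C>A]T
5	C[C>A]A
6	C[C>A]C
7	C[C>A]G
8	C[C>A]T
9	G[C>A]A
10	G[C>A]C
11	G[C>A]G
12	G[C>A]T
13	T[C>A]A
14	T[C>A]C
15	T[C>A]G
16	T[C>A]T
17	A[C>G]A
18	A[C>G]C
19	A[C>G]G
20	A[C>G]T
21	C[C>G]A
22	C[C>G]C
23	C[C>G]G
24	C[C>G]T
25	G[C>G]A
26	G[C>G]C
27	G[C>G]G
28	G[C>G]T
29	T[C>G]A
30	T[C>G]C
31	T[C>G]G
32	T[C>G]T
33	A[C>T]A
34	A[C>T]C
35	A[C>T]G
36	A[C>T]T
37	C[C>T]A
38	C[C>T]C
39	C[C>T]G
40	C[C>T]T
41	G[C>T]A
42	G[C>T]C
43	G[C>T]G
44	G[C>T]T
45	T[C>T]A
46	T[C>T]C
47	T[C>T]G
48	T[C>T]T
49	A[T>A]A
50	A[T>A]C
51	A[T>A]G
52	A[T>A]T
53	C[T>A]A
54	C[T>A]C
55	C[T>A]G
56	C[T>A]T
57	G[T>A]A
58	G[T>A]C
59	G[T>A]G
60	G[T>A]T
61	T[T>A]A
62	T[T>A]C
63	T[T>A]G
64	T[T>A]T
65	A[T>C]A
66	A[T>C]C
67	A[T>C]G
68	A[T>C]T
69	C[T>C]A
70	C[T>C]C
71	C[T>C]G
72	C[T>C]T
73	G[T>C]A
74	G[T>C]C
75	G[T>C]G
76	G[T>C]T
77	T[T>C]A
78	T[T>C]C
79	T[T>C]G
80	T[T>C]T
81	A[T>G]A
82	A[T>G]C
83	A[T>G]G
84	A[T>G]T
85	C[T>G]A
86	C[T>G]C
87	C[T>G]G
88	C[T>G]T
89	G[T>G]A
90	G[T>G]C
91	G[T>G]G
92	G[T>G]T
93	T[T>G]A
94	T[T>G]C
95	T[T>G]G
96	T[T>G]T
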