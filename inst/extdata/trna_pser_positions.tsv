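# Synthetic Sprinzl-position reconstruction of the orthogonal
# phosphoserine suppressor tRNA. The characterized features are
# faithful: acceptor pairs G1:C72 and C2:G71, discriminator U73,
# CUA anticodon (positions 34-36), short (non-extended) variable
# loop 44-48. All other positions are generic cloverleaf filler
# chosen only to keep the stems complementary.
sprinzl_position	base
1	G
2	C
3	G
4	G
5	C
6	G
7	G
8	U
9	G
10	G
11	C
12	U
13	C
14	A
15	G
16	U
17	U
18	G
19	G
20	U
21	A
22	G
23	A
24	G
25	C
26	A
27	C
28	C
29	U
30	G
31	G
32	C
33	U
34	C
35	U
36	A
37	A
38	A
39	C
40	C
41	A
42	G
43	G
44	G
45	G
46	U
47	C
48	C
49	G
50	G
51	G
52	U
53	G
54	U
55	U
56	C
57	G
58	A
59	A
60	U
61	C
62	A
63	C
64	C
65	C
66	C
67	C
68	G
69	C
70	C
71	G
72	C
73	U
74	C
75	C
76	A
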