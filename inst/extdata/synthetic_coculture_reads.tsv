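read_id	spacers	has_leader	has_trailer	novel
1	101,102,1,2,3	TRUE	TRUE	1,1,0,0,0
2	101,102,1,2	TRUE	FALSE	1,1,0,0
3	103,101	TRUE	FALSE	1,1
4	101	TRUE	FALSE	1
5	101,102	TRUE	FALSE	1,1
6	107	TRUE	FALSE	1
7	101,102,1,2,3	TRUE	TRUE	1,1,0,0,0
8	101,102,1,2,3	TRUE	TRUE	1,1,0,0,0
9	105,106,1,2,3	TRUE	TRUE	1,1,0,0,0
10	101,102,1,2	TRUE	FALSE	1,1,0,0
11	101,102,1,2,3	TRUE	TRUE	1,1,0,0,0
12	103,101,1,2	TRUE	FALSE	1,1,0,0
13	105,106,1,2,3	TRUE	TRUE	1,1,0,0,0
14	105,106,1,2,3	TRUE	TRUE	1,1,0,0,0
15	104,1,2,3	TRUE	TRUE	1,0,0,0
16	103,101,1,2,3	TRUE	TRUE	1,1,0,0,0
17	103,101,1,2	TRUE	FALSE	1,1,0,0
18	101,102	TRUE	FALSE	1,1
19	101,102	TRUE	FALSE	1,1
20	103,101,1,2,3	TRUE	TRUE	1,1,0,0,0
21	101,102,1,2,3	TRUE	TRUE	1,1,0,0,0
22	104,1,2,3	TRUE	TRUE	1,0,0,0
23	103,101,1,2,3	TRUE	TRUE	1,1,0,0,0
24	103,101,1,2,3	TRUE	TRUE	1,1,0,0,0
25	101,102,1,2,3	TRUE	TRUE	1,1,0,0,0
26	103,101,1,2,3	TRUE	TRUE	1,1,0,0,0
27	103,101,1,2,3	TRUE	TRUE	1,1,0,0,0
28	101,102,1,2,3	TRUE	TRUE	1,1,0,0,0
29	101	TRUE	FALSE	1
30	103,101,1,2,3	TRUE	TRUE	1,1,0,0,0
31	103,101,1	TRUE	FALSE	1,1,0
32	101,102,1,2,3	TRUE	TRUE	1,1,0,0,0
33	103	TRUE	FALSE	1
34	101,102,1,2,3	TRUE	TRUE	1,1,0,0,0
35	105,106,1,2,3	TRUE	TRUE	1,1,0,0,0
36	104	TRUE	FALSE	1
37	101,102	TRUE	FALSE	1,1
38	101,102,1	TRUE	FALSE	1,1,0
39	101,102,1,2,3	TRUE	TRUE	1,1,0,0,0
40	101,102,1,2,3	TRUE	TRUE	1,1,0,0,0
41	101,102,1,2,3	TRUE	TRUE	1,1,0,0,0
42	101,102,1,2,3	TRUE	TRUE	1,1,0,0,0
43	103,101,1	TRUE	FALSE	1,1,0
44	104,1,2,3	TRUE	TRUE	1,0,0,0
45	101,102	TRUE	FALSE	1,1
46	105,106,1,2,3	TRUE	TRUE	1,1,0,0,0
47	104,1,2	TRUE	FALSE	1,0,0
48	101	TRUE	FALSE	1
49	103,101,1,2,3	TRUE	TRUE	1,1,0,0,0
50	105,106,1,2,3	TRUE	TRUE	1,1,0,0,0
51	103	TRUE	FALSE	1
52	103,101,1,2,3	TRUE	TRUE	1,1,0,0,0
53	103,101,1,2,3	TRUE	TRUE	1,1,0,0,0
54	101	TRUE	FALSE	1
55	101,102,1,2,3	TRUE	TRUE	1,1,0,0,0
56	103,101,1,2,3	TRUE	TRUE	1,1,0,0,0
57	103,101,1,2,3	TRUE	TRUE	1,1,0,0,0
58	105,106,1,2,3	TRUE	TRUE	1,1,0,0,0
59	101,102,1,2,3	TRUE	TRUE	1,1,0,0,0
60	103,101,1,2,3	TRUE	TRUE	1,1,0,0,0
61	101,102,1,2,3	TRUE	TRUE	1,1,0,0,0
62	104,1,2,3	TRUE	TRUE	1,0,0,0
63	101,102,1,2,3	TRUE	TRUE	1,1,0,0,0
64	103	TRUE	FALSE	1
65	104,1	TRUE	FALSE	1,0
66	101,102,1,2,3	TRUE	TRUE	1,1,0,0,0
67	101,102,1,2,3	TRUE	TRUE	1,1,0,0,0
68	103,101,1,2,3	TRUE	TRUE	1,1,0,0,0
69	101,102,1	TRUE	FALSE	1,1,0
70	104,1,2,3	TRUE	TRUE	1,0,0,0
71	104,1,2,3	TRUE	TRUE	1,0,0,0
72	103,101,1,2	TRUE	FALSE	1,1,0,0
73	103,101,1,2,3	TRUE	TRUE	1,1,0,0,0
74	101,102,1,2,3	TRUE	TRUE	1,1,0,0,0
75	107,1,2,3	TRUE	TRUE	1,0,0,0
76	103,101	TRUE	FALSE	1,1
77	101,102,1,2,3	TRUE	TRUE	1,1,0,0,0
78	101	TRUE	FALSE	1
79	103,101,1,2	TRUE	FALSE	1,1,0,0
80	101,102	TRUE	FALSE	1,1
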