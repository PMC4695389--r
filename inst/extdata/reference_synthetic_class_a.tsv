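index	residue	bw
1	Q	
2	R	
3	A	
4	D	
5	S	
6	N	
7	H	
8	P	
9	K	
10	T	
11	E	
12	G	
13	Q	
14	R	
15	A	
16	D	
17	S	
18	N	
19	H	
20	P	
21	K	
22	T	
23	E	
24	G	
25	Q	
26	W	1.30
27	V	1.31
28	V	1.32
29	G	1.33
30	M	1.34
31	A	1.35
32	I	1.36
33	L	1.37
34	C	1.38
35	V	1.39
36	L	1.40
37	I	1.41
38	V	1.42
39	T	1.43
40	S	1.44
41	I	1.45
42	V	1.46
43	L	1.47
44	A	1.48
45	G	1.49
46	N	1.50
47	L	1.51
48	V	1.52
49	M	1.53
50	L	1.54
51	S	1.55
52	V	1.56
53	F	1.57
54	T	1.58
55	Q	1.59
56	N	
57	H	
58	P	
59	K	
60	T	
61	E	
62	L	2.38
63	N	2.39
64	L	2.40
65	F	2.41
66	V	2.42
67	L	2.43
68	S	2.44
69	L	2.45
70	A	2.46
71	V	2.47
72	A	2.48
73	D	2.49
74	D	2.50
75	L	2.51
76	V	2.52
77	A	2.53
78	L	2.54
79	L	2.55
80	V	2.56
81	M	2.57
82	P	2.58
83	F	2.59
84	S	2.60
85	L	2.61
86	A	2.62
87	N	2.63
88	E	2.64
89	L	2.65
90	E	
91	G	
92	Q	
93	R	
94	A	
95	D	
96	W	3.22
97	L	3.23
98	F	3.24
99	G	3.25
100	A	3.26
101	F	3.27
102	L	3.28
103	C	3.29
104	E	3.30
105	L	3.31
106	D	3.32
107	V	3.33
108	A	3.34
109	M	3.35
110	D	3.36
111	V	3.37
112	M	3.38
113	L	3.39
114	C	3.40
115	T	3.41
116	A	3.42
117	S	3.43
118	I	3.44
119	F	3.45
120	N	3.46
121	L	3.47
122	C	3.48
123	D	3.49
124	R	3.50
125	Y	3.51
126	W	3.52
127	A	3.53
128	I	3.54
129	T	3.55
130	D	
131	S	
132	N	
133	H	
134	P	
135	K	
136	T	
137	E	
138	R	4.39
139	V	4.40
140	A	4.41
141	V	4.42
142	M	4.43
143	I	4.44
144	A	4.45
145	A	4.46
146	V	4.47
147	W	4.48
148	L	4.49
149	W	4.50
150	S	4.51
151	L	4.52
152	L	4.53
153	V	4.54
154	T	4.55
155	F	4.56
156	P	4.57
157	P	4.58
158	L	4.59
159	L	4.60
160	G	4.61
161	W	4.62
162	K	
163	T	
164	E	
165	G	
166	Q	
167	R	
168	A	
169	D	
170	S	
171	N	
172	H	
173	P	
174	K	
175	T	
176	E	
177	G	
178	Q	
179	R	
180	A	
181	D	
182	N	5.35
183	F	5.36
184	V	5.37
185	I	5.38
186	A	5.39
187	Y	5.40
188	T	5.41
189	S	5.42
190	S	5.43
191	V	5.44
192	I	5.45
193	S	5.46
194	F	5.47
195	Y	5.48
196	I	5.49
197	P	5.50
198	L	5.51
199	A	5.52
200	V	5.53
201	M	5.54
202	L	5.55
203	V	5.56
204	M	5.57
205	Y	5.58
206	G	5.59
207	R	5.60
208	I	5.61
209	Y	5.62
210	V	5.63
211	T	5.64
212	A	5.65
213	R	5.66
214	R	5.67
215	R	
216	A	
217	D	
218	S	
219	N	
220	H	
221	P	
222	K	
223	T	
224	E	
225	G	
226	Q	
227	R	
228	A	
229	D	
230	S	
231	N	
232	H	
233	K	6.30
234	A	6.31
235	A	6.32
236	K	6.33
237	T	6.34
238	L	6.35
239	G	6.36
240	I	6.37
241	V	6.38
242	M	6.39
243	G	6.40
244	V	6.41
245	F	6.42
246	I	6.43
247	L	6.44
248	C	6.45
249	T	6.46
250	L	6.47
251	W	6.48
252	L	6.49
253	P	6.50
254	F	6.51
255	F	6.52
256	L	6.53
257	A	6.54
258	N	6.55
259	V	6.56
260	I	6.57
261	N	6.58
262	R	6.59
263	F	6.60
264	Y	6.61
265	H	
266	P	
267	K	
268	T	
269	E	
270	E	7.32
271	M	7.33
272	W	7.34
273	I	7.35
274	G	7.36
275	Y	7.37
276	L	7.38
277	N	7.39
278	S	7.40
279	G	7.41
280	L	7.42
281	N	7.43
282	P	7.44
283	V	7.45
284	I	7.46
285	Y	7.47
286	T	7.48
287	N	7.49
288	P	7.50
289	S	7.51
290	M	7.52
291	Y	7.53
292	A	7.54
293	R	7.55
294	G	
295	Q	
296	R	
297	A	
298	D	
299	S	
300	N	
301	H	
302	P	
303	K	
304	T	
305	E	
306	G	
307	Q	
308	R	
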