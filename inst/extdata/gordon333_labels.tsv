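roi_id	network
1	Aud
2	Aud
3	Aud
4	Aud
5	Aud
6	Aud
7	Aud
8	Aud
9	Aud
10	Aud
11	Aud
12	Aud
13	Aud
14	Aud
15	Aud
16	Aud
17	Aud
18	Aud
19	Aud
20	Aud
21	Aud
22	Aud
23	Aud
24	Aud
25	CiO
26	CiO
27	CiO
28	CiO
29	CiO
30	CiO
31	CiO
32	CiO
33	CiO
34	CiO
35	CiO
36	CiO
37	CiO
38	CiO
39	CiO
40	CiO
41	CiO
42	CiO
43	CiO
44	CiO
45	CiO
46	CiO
47	CiO
48	CiO
49	CiO
50	CiO
51	CiO
52	CiO
53	CiO
54	CiO
55	CiO
56	CiO
57	CiO
58	CiO
59	CiO
60	CiO
61	CiO
62	CiO
63	CiO
64	CiO
65	CiP
66	CiP
67	CiP
68	CiP
69	CiP
70	Def
71	Def
72	Def
73	Def
74	Def
75	Def
76	Def
77	Def
78	Def
79	Def
80	Def
81	Def
82	Def
83	Def
84	Def
85	Def
86	Def
87	Def
88	Def
89	Def
90	Def
91	Def
92	Def
93	Def
94	Def
95	Def
96	Def
97	Def
98	Def
99	Def
100	Def
101	Def
102	Def
103	Def
104	Def
105	Def
106	Def
107	Def
108	Def
109	Def
110	Def
111	DoA
112	DoA
113	DoA
114	DoA
115	DoA
116	DoA
117	DoA
118	DoA
119	DoA
120	DoA
121	DoA
122	DoA
123	DoA
124	DoA
125	DoA
126	DoA
127	DoA
128	DoA
129	DoA
130	DoA
131	DoA
132	DoA
133	DoA
134	DoA
135	DoA
136	DoA
137	DoA
138	DoA
139	DoA
140	DoA
141	DoA
142	DoA
143	FrP
144	FrP
145	FrP
146	FrP
147	FrP
148	FrP
149	FrP
150	FrP
151	FrP
152	FrP
153	FrP
154	FrP
155	FrP
156	FrP
157	FrP
158	FrP
159	FrP
160	FrP
161	FrP
162	FrP
163	FrP
164	FrP
165	FrP
166	FrP
167	ReT
168	ReT
169	ReT
170	ReT
171	ReT
172	ReT
173	ReT
174	ReT
175	SMl
176	SMl
177	SMl
178	SMl
179	SMl
180	SMl
181	SMl
182	SMl
183	SMl
184	SMl
185	SMl
186	SMl
187	SMl
188	SMl
189	SMl
190	SMl
191	SMl
192	SMl
193	SMl
194	SMl
195	SMl
196	SMl
197	SMl
198	SMl
199	SMl
200	SMl
201	SMl
202	SMl
203	SMl
204	SMl
205	SMl
206	SMl
207	SMl
208	SMl
209	SMl
210	SMl
211	SMl
212	SMl
213	SMm
214	SMm
215	SMm
216	SMm
217	SMm
218	SMm
219	SMm
220	SMm
221	Sal
222	Sal
223	Sal
224	Sal
225	VeA
226	VeA
227	VeA
228	VeA
229	VeA
230	VeA
231	VeA
232	VeA
233	VeA
234	VeA
235	VeA
236	VeA
237	VeA
238	VeA
239	VeA
240	VeA
241	VeA
242	VeA
243	VeA
244	VeA
245	VeA
246	VeA
247	VeA
248	Vis
249	Vis
250	Vis
251	Vis
252	Vis
253	Vis
254	Vis
255	Vis
256	Vis
257	Vis
258	Vis
259	Vis
260	Vis
261	Vis
262	Vis
263	Vis
264	Vis
265	Vis
266	Vis
267	Vis
268	Vis
269	Vis
270	Vis
271	Vis
272	Vis
273	Vis
274	Vis
275	Vis
276	Vis
277	Vis
278	Vis
279	Vis
280	Vis
281	Vis
282	Vis
283	Vis
284	Vis
285	Vis
286	Vis
287	None
288	None
289	None
290	None
291	None
292	None
293	None
294	None
295	None
296	None
297	None
298	None
299	None
300	None
301	None
302	None
303	None
304	None
305	None
306	None
307	None
308	None
309	None
310	None
311	None
312	None
313	None
314	None
315	None
316	None
317	None
318	None
319	None
320	None
321	None
322	None
323	None
324	None
325	None
326	None
327	None
328	None
329	None
330	None
331	None
332	None
333	None
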