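node_id	node_label	network_label
1	VIS_001	VIS
2	VIS_002	VIS
3	VIS_003	VIS
4	VIS_004	VIS
5	VIS_005	VIS
6	VIS_006	VIS
7	VIS_007	VIS
8	VIS_008	VIS
9	VIS_009	VIS
10	VIS_010	VIS
11	VIS_011	VIS
12	VIS_012	VIS
13	VIS_013	VIS
14	VIS_014	VIS
15	VIS_015	VIS
16	VIS_016	VIS
17	VIS_017	VIS
18	VIS_018	VIS
19	VIS_019	VIS
20	VIS_020	VIS
21	VIS_021	VIS
22	VIS_022	VIS
23	VIS_023	VIS
24	VIS_024	VIS
25	VIS_025	VIS
26	VIS_026	VIS
27	VIS_027	VIS
28	VIS_028	VIS
29	VIS_029	VIS
30	VIS_030	VIS
31	SMN_001	SMN
32	SMN_002	SMN
33	SMN_003	SMN
34	SMN_004	SMN
35	SMN_005	SMN
36	SMN_006	SMN
37	SMN_007	SMN
38	SMN_008	SMN
39	SMN_009	SMN
40	SMN_010	SMN
41	SMN_011	SMN
42	SMN_012	SMN
43	SMN_013	SMN
44	SMN_014	SMN
45	SMN_015	SMN
46	SMN_016	SMN
47	SMN_017	SMN
48	SMN_018	SMN
49	SMN_019	SMN
50	SMN_020	SMN
51	SMN_021	SMN
52	SMN_022	SMN
53	SMN_023	SMN
54	SMN_024	SMN
55	SMN_025	SMN
56	SMN_026	SMN
57	SMN_027	SMN
58	SMN_028	SMN
59	SMN_029	SMN
60	SMN_030	SMN
61	SMN_031	SMN
62	SMN_032	SMN
63	SMN_033	SMN
64	SMN_034	SMN
65	SMN_035	SMN
66	SMN_036	SMN
67	SMN_037	SMN
68	SMN_038	SMN
69	DAN_001	DAN
70	DAN_002	DAN
71	DAN_003	DAN
72	DAN_004	DAN
73	DAN_005	DAN
74	DAN_006	DAN
75	DAN_007	DAN
76	DAN_008	DAN
77	DAN_009	DAN
78	DAN_010	DAN
79	DAN_011	DAN
80	DAN_012	DAN
81	DAN_013	DAN
82	DAN_014	DAN
83	DAN_015	DAN
84	DAN_016	DAN
85	DAN_017	DAN
86	DAN_018	DAN
87	DAN_019	DAN
88	DAN_020	DAN
89	DAN_021	DAN
90	DAN_022	DAN
91	DAN_023	DAN
92	DAN_024	DAN
93	DAN_025	DAN
94	DAN_026	DAN
95	VAN_001	VAN
96	VAN_002	VAN
97	VAN_003	VAN
98	VAN_004	VAN
99	VAN_005	VAN
100	VAN_006	VAN
101	VAN_007	VAN
102	VAN_008	VAN
103	VAN_009	VAN
104	VAN_010	VAN
105	VAN_011	VAN
106	VAN_012	VAN
107	VAN_013	VAN
108	VAN_014	VAN
109	VAN_015	VAN
110	VAN_016	VAN
111	VAN_017	VAN
112	VAN_018	VAN
113	VAN_019	VAN
114	VAN_020	VAN
115	VAN_021	VAN
116	VAN_022	VAN
117	VAN_023	VAN
118	VAN_024	VAN
119	LIM_001	LIM
120	LIM_002	LIM
121	LIM_003	LIM
122	LIM_004	LIM
123	LIM_005	LIM
124	LIM_006	LIM
125	LIM_007	LIM
126	LIM_008	LIM
127	LIM_009	LIM
128	LIM_010	LIM
129	LIM_011	LIM
130	LIM_012	LIM
131	LIM_013	LIM
132	LIM_014	LIM
133	LIM_015	LIM
134	LIM_016	LIM
135	LIM_017	LIM
136	LIM_018	LIM
137	LIM_019	LIM
138	LIM_020	LIM
139	LIM_021	LIM
140	LIM_022	LIM
141	FPN_001	FPN
142	FPN_002	FPN
143	FPN_003	FPN
144	FPN_004	FPN
145	FPN_005	FPN
146	FPN_006	FPN
147	FPN_007	FPN
148	FPN_008	FPN
149	FPN_009	FPN
150	FPN_010	FPN
151	FPN_011	FPN
152	FPN_012	FPN
153	FPN_013	FPN
154	FPN_014	FPN
155	FPN_015	FPN
156	FPN_016	FPN
157	FPN_017	FPN
158	FPN_018	FPN
159	FPN_019	FPN
160	FPN_020	FPN
161	FPN_021	FPN
162	FPN_022	FPN
163	FPN_023	FPN
164	FPN_024	FPN
165	FPN_025	FPN
166	FPN_026	FPN
167	FPN_027	FPN
168	FPN_028	FPN
169	DMN_001	DMN
170	DMN_002	DMN
171	DMN_003	DMN
172	DMN_004	DMN
173	DMN_005	DMN
174	DMN_006	DMN
175	DMN_007	DMN
176	DMN_008	DMN
177	DMN_009	DMN
178	DMN_010	DMN
179	DMN_011	DMN
180	DMN_012	DMN
181	DMN_013	DMN
182	DMN_014	DMN
183	DMN_015	DMN
184	DMN_016	DMN
185	DMN_017	DMN
186	DMN_018	DMN
187	DMN_019	DMN
188	DMN_020	DMN
189	DMN_021	DMN
190	DMN_022	DMN
191	DMN_023	DMN
192	DMN_024	DMN
193	DMN_025	DMN
194	DMN_026	DMN
195	DMN_027	DMN
196	DMN_028	DMN
197	DMN_029	DMN
198	DMN_030	DMN
199	DMN_031	DMN
200	DMN_032	DMN
201	DMN_033	DMN
202	DMN_034	DMN
203	DMN_035	DMN
204	DMN_036	DMN
205	DMN_037	DMN
206	DMN_038	DMN
207	DMN_039	DMN
208	DMN_040	DMN
209	DMN_041	DMN
210	DMN_042	DMN
211	SUB_001	SUB
212	SUB_002	SUB
213	SUB_003	SUB
214	SUB_004	SUB
215	SUB_005	SUB
216	SUB_006	SUB
217	SUB_007	SUB
218	SUB_008	SUB
219	SUB_009	SUB
220	SUB_010	SUB
221	SUB_011	SUB
222	SUB_012	SUB
223	SUB_013	SUB
224	SUB_014	SUB
225	SUB_015	SUB
226	SUB_016	SUB
227	SUB_017	SUB
228	SUB_018	SUB
229	SUB_019	SUB
230	SUB_020	SUB
231	SUB_021	SUB
232	SUB_022	SUB
233	SUB_023	SUB
234	SUB_024	SUB
235	SUB_025	SUB
236	SUB_026	SUB
237	SUB_027	SUB
238	SUB_028	SUB
239	SUB_029	SUB
240	SUB_030	SUB
241	SUB_031	SUB
242	SUB_032	SUB
243	SUB_033	SUB
244	SUB_034	SUB
245	SUB_035	SUB
246	SUB_036	SUB
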