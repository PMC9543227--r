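index,name,hemisphere,lobe
0,SFG_L_1,L,frontal
1,SFG_R_1,R,frontal
2,SFG_L_2,L,frontal
3,SFG_R_2,R,frontal
4,SFG_L_3,L,frontal
5,SFG_R_3,R,frontal
6,SFG_L_4,L,frontal
7,SFG_R_4,R,frontal
8,SFG_L_5,L,frontal
9,SFG_R_5,R,frontal
10,SFG_L_6,L,frontal
11,SFG_R_6,R,frontal
12,SFG_L_7,L,frontal
13,SFG_R_7,R,frontal
14,SFG_L_8,L,frontal
15,SFG_R_8,R,frontal
16,MFG_L_1,L,frontal
17,MFG_R_1,R,frontal
18,MFG_L_2,L,frontal
19,MFG_R_2,R,frontal
20,MFG_L_3,L,frontal
21,MFG_R_3,R,frontal
22,MFG_L_4,L,frontal
23,MFG_R_4,R,frontal
24,MFG_L_5,L,frontal
25,MFG_R_5,R,frontal
26,MFG_L_6,L,frontal
27,MFG_R_6,R,frontal
28,MFG_L_7,L,frontal
29,MFG_R_7,R,frontal
30,MFG_L_8,L,frontal
31,MFG_R_8,R,frontal
32,IFG_L_1,L,frontal
33,IFG_R_1,R,frontal
34,IFG_L_2,L,frontal
35,IFG_R_2,R,frontal
36,IFG_L_3,L,frontal
37,IFG_R_3,R,frontal
38,IFG_L_4,L,frontal
39,IFG_R_4,R,frontal
40,IFG_L_5,L,frontal
41,IFG_R_5,R,frontal
42,IFG_L_6,L,frontal
43,IFG_R_6,R,frontal
44,IFG_L_7,L,frontal
45,IFG_R_7,R,frontal
46,OrG_L_1,L,frontal
47,OrG_R_1,R,frontal
48,OrG_L_2,L,frontal
49,OrG_R_2,R,frontal
50,OrG_L_3,L,frontal
51,OrG_R_3,R,frontal
52,OrG_L_4,L,frontal
53,OrG_R_4,R,frontal
54,OrG_L_5,L,frontal
55,OrG_R_5,R,frontal
56,OrG_L_6,L,frontal
57,OrG_R_6,R,frontal
58,OrG_L_7,L,frontal
59,OrG_R_7,R,frontal
60,STG_L_1,L,temporal
61,STG_R_1,R,temporal
62,STG_L_2,L,temporal
63,STG_R_2,R,temporal
64,STG_L_3,L,temporal
65,STG_R_3,R,temporal
66,STG_L_4,L,temporal
67,STG_R_4,R,temporal
68,STG_L_5,L,temporal
69,STG_R_5,R,temporal
70,STG_L_6,L,temporal
71,STG_R_6,R,temporal
72,MTG_L_1,L,temporal
73,MTG_R_1,R,temporal
74,MTG_L_2,L,temporal
75,MTG_R_2,R,temporal
76,MTG_L_3,L,temporal
77,MTG_R_3,R,temporal
78,MTG_L_4,L,temporal
79,MTG_R_4,R,temporal
80,MTG_L_5,L,temporal
81,MTG_R_5,R,temporal
82,MTG_L_6,L,temporal
83,MTG_R_6,R,temporal
84,ITG_L_1,L,temporal
85,ITG_R_1,R,temporal
86,ITG_L_2,L,temporal
87,ITG_R_2,R,temporal
88,ITG_L_3,L,temporal
89,ITG_R_3,R,temporal
90,ITG_L_4,L,temporal
91,ITG_R_4,R,temporal
92,FuG_L_1,L,temporal
93,FuG_R_1,R,temporal
94,FuG_L_2,L,temporal
95,FuG_R_2,R,temporal
96,pSTS_L_1,L,temporal
97,pSTS_R_1,R,temporal
98,pSTS_L_2,L,temporal
99,pSTS_R_2,R,temporal
100,PrG_L_1,L,central
101,PrG_R_1,R,central
102,PrG_L_2,L,central
103,PrG_R_2,R,central
104,PrG_L_3,L,central
105,PrG_R_3,R,central
106,PrG_L_4,L,central
107,PrG_R_4,R,central
108,PrG_L_5,L,central
109,PrG_R_5,R,central
110,PrG_L_6,L,central
111,PrG_R_6,R,central
112,PoG_L_1,L,central
113,PoG_R_1,R,central
114,PoG_L_2,L,central
115,PoG_R_2,R,central
116,PoG_L_3,L,central
117,PoG_R_3,R,central
118,PoG_L_4,L,central
119,PoG_R_4,R,central
120,PoG_L_5,L,central
121,PoG_R_5,R,central
122,PoG_L_6,L,central
123,PoG_R_6,R,central
124,SPL_L_1,L,parietal
125,SPL_R_1,R,parietal
126,SPL_L_2,L,parietal
127,SPL_R_2,R,parietal
128,SPL_L_3,L,parietal
129,SPL_R_3,R,parietal
130,SPL_L_4,L,parietal
131,SPL_R_4,R,parietal
132,SPL_L_5,L,parietal
133,SPL_R_5,R,parietal
134,IPL_L_1,L,parietal
135,IPL_R_1,R,parietal
136,IPL_L_2,L,parietal
137,IPL_R_2,R,parietal
138,IPL_L_3,L,parietal
139,IPL_R_3,R,parietal
140,IPL_L_4,L,parietal
141,IPL_R_4,R,parietal
142,IPL_L_5,L,parietal
143,IPL_R_5,R,parietal
144,IPL_L_6,L,parietal
145,IPL_R_6,R,parietal
146,IPL_L_7,L,parietal
147,IPL_R_7,R,parietal
148,Pcun_L_1,L,parietal
149,Pcun_R_1,R,parietal
150,Pcun_L_2,L,parietal
151,Pcun_R_2,R,parietal
152,Pcun_L_3,L,parietal
153,Pcun_R_3,R,parietal
154,Pcun_L_4,L,parietal
155,Pcun_R_4,R,parietal
156,MVOcC_L_1,L,occipital
157,MVOcC_R_1,R,occipital
158,MVOcC_L_2,L,occipital
159,MVOcC_R_2,R,occipital
160,MVOcC_L_3,L,occipital
161,MVOcC_R_3,R,occipital
162,MVOcC_L_4,L,occipital
163,MVOcC_R_4,R,occipital
164,MVOcC_L_5,L,occipital
165,MVOcC_R_5,R,occipital
166,LOcC_L_1,L,occipital
167,LOcC_R_1,R,occipital
168,LOcC_L_2,L,occipital
169,LOcC_R_2,R,occipital
170,LOcC_L_3,L,occipital
171,LOcC_R_3,R,occipital
172,LOcC_L_4,L,occipital
173,LOcC_R_4,R,occipital
174,LOcC_L_5,L,occipital
175,LOcC_R_5,R,occipital
176,LOcC_L_6,L,occipital
177,LOcC_R_6,R,occipital
178,LOcC_L_7,L,occipital
179,LOcC_R_7,R,occipital
180,CG_L_1,L,limbic
181,CG_R_1,R,limbic
182,CG_L_2,L,limbic
183,CG_R_2,R,limbic
184,CG_L_3,L,limbic
185,CG_R_3,R,limbic
186,CG_L_4,L,limbic
187,CG_R_4,R,limbic
188,CG_L_5,L,limbic
189,CG_R_5,R,limbic
190,CG_L_6,L,limbic
191,CG_R_6,R,limbic
192,CG_L_7,L,limbic
193,CG_R_7,R,limbic
194,PhG_L_1,L,limbic
195,PhG_R_1,R,limbic
196,PhG_L_2,L,limbic
197,PhG_R_2,R,limbic
198,PhG_L_3,L,limbic
199,PhG_R_3,R,limbic
200,INS_L_1,L,insular
201,INS_R_1,R,insular
202,INS_L_2,L,insular
203,INS_R_2,R,insular
204,INS_L_3,L,insular
205,INS_R_3,R,insular
206,INS_L_4,L,insular
207,INS_R_4,R,insular
208,INS_L_5,L,insular
209,INS_R_5,R,insular
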