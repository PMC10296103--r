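label	name	hemisphere	lobe
1	Precentral Gyrus	L	Frontal
2	Precentral Gyrus	R	Frontal
3	Superior Frontal Gyrus: Dorsolateral	L	Frontal
4	Superior Frontal Gyrus: Dorsolateral	R	Frontal
5	Superior Frontal Gyrus: Orbital Part	L	Frontal
6	Superior Frontal Gyrus: Orbital Part	R	Frontal
7	Middle Frontal Gyrus	L	Frontal
8	Middle Frontal Gyrus	R	Frontal
9	Middle Frontal Gyrus: Orbital Part	L	Frontal
10	Middle Frontal Gyrus: Orbital Part	R	Frontal
11	Inferior Frontal Gyrus: Opercular Part	L	Frontal
12	Inferior Frontal Gyrus: Opercular Part	R	Frontal
13	Inferior Frontal Gyrus: Triangular Part	L	Frontal
14	Inferior Frontal Gyrus: Triangular Part	R	Frontal
15	Inferior Frontal Gyrus: Orbital Part	L	Frontal
16	Inferior Frontal Gyrus: Orbital Part	R	Frontal
17	Rolandic Operculum	L	Frontal
18	Rolandic Operculum	R	Frontal
19	Supplementary Motor Area	L	Frontal
20	Supplementary Motor Area	R	Frontal
21	Olfactory Cortex	L	Frontal
22	Olfactory Cortex	R	Frontal
23	Superior Frontal Gyrus: Medial	L	Frontal
24	Superior Frontal Gyrus: Medial	R	Frontal
25	Superior Frontal Gyrus: Medial Orbital	L	Frontal
26	Superior Frontal Gyrus: Medial Orbital	R	Frontal
27	Gyrus Rectus	L	Frontal
28	Gyrus Rectus	R	Frontal
29	Paracentral Lobule	L	Frontal
30	Paracentral Lobule	R	Frontal
31	Insula	L	Insula and Cingulate
32	Insula	R	Insula and Cingulate
33	Anterior Cingulate and Paracingulate Gyri	L	Insula and Cingulate
34	Anterior Cingulate and Paracingulate Gyri	R	Insula and Cingulate
35	Median Cingulate and Paracingulate Gyri	L	Insula and Cingulate
36	Median Cingulate and Paracingulate Gyri	R	Insula and Cingulate
37	Posterior Cingulate Gyrus	L	Insula and Cingulate
38	Posterior Cingulate Gyrus	R	Insula and Cingulate
39	Calcarine Fissure and Surrounding Cortex	L	Occipital
40	Calcarine Fissure and Surrounding Cortex	R	Occipital
41	Cuneus	L	Occipital
42	Cuneus	R	Occipital
43	Lingual Gyrus	L	Occipital
44	Lingual Gyrus	R	Occipital
45	Superior Occipital Gyrus	L	Occipital
46	Superior Occipital Gyrus	R	Occipital
47	Middle Occipital Gyrus	L	Occipital
48	Middle Occipital Gyrus	R	Occipital
49	Inferior Occipital Gyrus	L	Occipital
50	Inferior Occipital Gyrus	R	Occipital
51	Fusiform Gyrus	L	Occipital
52	Fusiform Gyrus	R	Occipital
53	Postcentral Gyrus	L	Parietal
54	Postcentral Gyrus	R	Parietal
55	Superior Parietal Gyrus	L	Parietal
56	Superior Parietal Gyrus	R	Parietal
57	Inferior Parietal Gyrus	L	Parietal
58	Inferior Parietal Gyrus	R	Parietal
59	Supramarginal Gyrus	L	Parietal
60	Supramarginal Gyrus	R	Parietal
61	Angular Gyrus	L	Parietal
62	Angular Gyrus	R	Parietal
63	Precuneus	L	Parietal
64	Precuneus	R	Parietal
65	Heschl Gyrus	L	Temporal
66	Heschl Gyrus	R	Temporal
67	Superior Temporal Gyrus	L	Temporal
68	Superior Temporal Gyrus	R	Temporal
69	Temporal Pole: Superior Temporal Gyrus	L	Temporal
70	Temporal Pole: Superior Temporal Gyrus	R	Temporal
71	Middle Temporal Gyrus	L	Temporal
72	Middle Temporal Gyrus	R	Temporal
73	Temporal Pole: Middle Temporal Gyrus	L	Temporal
74	Temporal Pole: Middle Temporal Gyrus	R	Temporal
75	Inferior Temporal Gyrus	L	Temporal
76	Inferior Temporal Gyrus	R	Temporal
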