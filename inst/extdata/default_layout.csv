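# Default sensor layout: 128 channels on a 12x12 grid (1-based; row 1 = front,
# cols 1-6 left hemisphere, 7-12 right). Cells (1,3) and (1,10) are reserved
# empty prefrontal reference positions. 14 channels are doubled to fill the
# 142 cells symmetrically. The montage vendor does not publish the exact
# channel-to-cell table, so this assignment is a documented, replaceable
# default constructed to respect the region layout and mirror symmetry.
channel_id,row,col,region
1,1,1,prefrontal
2,1,2,prefrontal
3,1,4,prefrontal
4,1,5,prefrontal
5,1,6,prefrontal
6,1,7,prefrontal
7,1,8,prefrontal
8,1,9,prefrontal
9,1,11,prefrontal
10,1,12,prefrontal
11,2,1,frontal
12,2,2,frontal
13,2,3,frontal
14,2,4,frontal
15,2,5,frontal
16,2,6,frontal
17,2,7,frontal
18,2,8,frontal
19,2,9,frontal
20,2,10,frontal
21,2,11,frontal
22,2,12,frontal
23,3,1,frontal
24,3,2,frontal
25,3,3,frontal
26,3,4,frontal
27,3,5,frontal
28,3,6,frontal
29,3,7,frontal
30,3,8,frontal
31,3,9,frontal
32,3,10,frontal
33,3,11,frontal
34,3,12,frontal
35,4,1,temporal-L
36,4,2,temporal-L
37,4,3,central
38,4,4,central
39,4,5,central
40,4,6,central
41,4,7,central
42,4,8,central
43,4,9,central
44,4,10,central
45,4,11,temporal-R
46,4,12,temporal-R
47,5,1,temporal-L
48,5,2,temporal-L
49,5,3,central
50,5,4,central
51,5,5,central
52,5,6,central
53,5,7,central
54,5,8,central
55,5,9,central
56,5,10,central
57,5,11,temporal-R
58,5,12,temporal-R
59,6,1,temporal-L
60,6,2,temporal-L
61,6,3,central
62,6,4,central
63,6,5,central
64,6,6,central
65,6,7,central
66,6,8,central
67,6,9,central
68,6,10,central
69,6,11,temporal-R
70,6,12,temporal-R
71,7,1,temporal-L
72,7,2,temporal-L
73,7,3,parietal
74,7,4,parietal
75,7,5,parietal
76,7,6,parietal
77,7,7,parietal
78,7,8,parietal
79,7,9,parietal
80,7,10,parietal
81,7,11,temporal-R
82,7,12,temporal-R
83,8,1,temporal-L
84,8,2,temporal-L
85,8,3,parietal
86,8,4,parietal
87,8,5,parietal
88,8,6,parietal
89,8,7,parietal
90,8,8,parietal
91,8,9,parietal
92,8,10,parietal
93,8,11,temporal-R
94,8,12,temporal-R
95,9,1,temporal-L
96,9,2,temporal-L
97,9,3,parietal
98,9,4,parietal
99,9,5,parietal
100,9,6,parietal
101,9,7,parietal
102,9,8,parietal
103,9,9,parietal
104,9,10,parietal
105,9,11,temporal-R
106,9,12,temporal-R
107,10,1,occipital
108,10,2,occipital
109,10,3,occipital
110,10,4,occipital
111,10,5,occipital
112,10,6,occipital
113,10,7,occipital
114,10,8,occipital
115,10,9,occipital
116,10,10,occipital
117,10,11,occipital
118,10,12,occipital
119,11,1,occipital
120,11,2,occipital
121,11,3,occipital
122,11,4,occipital
123,11,5,occipital
124,11,6,occipital
125,11,7,occipital
126,11,8,occipital
127,11,9,occipital
128,11,10,occipital
120,11,11,occipital
119,11,12,occipital
107,12,1,occipital
108,12,2,occipital
109,12,3,occipital
110,12,4,occipital
111,12,5,occipital
112,12,6,occipital
113,12,7,occipital
114,12,8,occipital
115,12,9,occipital
116,12,10,occipital
117,12,11,occipital
118,12,12,occipital
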