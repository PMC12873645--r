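trial,session,block,true_state,ball_color,bounce,room_color,u,c
1,1,1,1,red,low,pink,1,1
2,1,1,1,red,low,pink,1,1
3,1,1,1,red,low,pink,1,1
4,1,1,1,green,high,pink,1,1
5,1,1,1,red,high,pink,0,1
6,1,1,1,green,high,pink,1,1
7,1,1,1,red,low,pink,1,1
8,1,1,1,red,low,pink,1,1
9,1,1,1,green,low,pink,0,1
10,1,1,1,red,low,pink,1,1
11,1,1,1,red,low,pink,1,1
12,1,1,1,red,low,pink,1,1
13,1,1,1,green,high,pink,1,1
14,1,1,1,green,high,pink,1,1
15,1,1,1,red,low,pink,1,1
16,1,1,1,red,high,pink,0,1
17,1,1,1,red,low,pink,1,1
18,1,1,1,green,high,pink,1,1
19,1,1,1,green,high,pink,1,1
20,1,1,1,red,low,pink,1,1
21,1,1,1,green,high,pink,1,1
22,1,1,1,red,low,pink,1,1
23,1,2,0,red,high,orange,0,0
24,1,2,0,green,low,orange,0,0
25,1,2,0,red,high,orange,0,0
26,1,2,0,red,low,orange,1,0
27,1,2,0,red,high,orange,0,0
28,1,2,0,red,high,orange,0,0
29,1,2,0,green,low,orange,0,0
30,1,2,0,red,low,orange,1,0
31,1,2,0,red,high,orange,0,0
32,1,2,0,green,low,orange,0,0
33,1,2,0,green,low,orange,0,0
34,1,2,0,red,high,orange,0,0
35,1,2,0,red,high,orange,0,0
36,1,2,0,green,high,orange,1,0
37,1,2,0,green,low,orange,0,0
38,1,2,0,green,low,orange,0,0
39,1,2,0,green,high,orange,1,0
40,1,2,0,red,high,orange,0,0
41,1,2,0,green,low,orange,0,0
42,1,2,0,green,low,orange,0,0
43,1,2,0,red,high,orange,0,0
44,1,2,0,red,high,orange,0,0
45,1,2,0,green,low,orange,0,0
46,1,2,0,green,low,orange,0,0
47,1,2,0,green,low,orange,0,0
48,1,2,0,green,low,orange,0,0
49,1,3,1,red,low,pink,1,1
50,1,3,1,red,low,pink,1,1
51,1,3,1,red,low,pink,1,1
52,1,3,1,green,high,pink,1,1
53,1,3,1,red,low,pink,1,1
54,1,3,1,red,low,pink,1,1
55,1,3,1,green,high,pink,1,1
56,1,3,1,red,low,pink,1,1
57,1,3,1,red,low,pink,1,1
58,1,3,1,red,low,pink,1,1
59,1,3,1,red,low,pink,1,1
60,1,3,1,red,low,pink,1,1
61,1,3,1,green,high,pink,1,1
62,1,3,1,red,low,pink,1,1
63,1,3,1,red,low,pink,1,1
64,1,3,1,green,high,pink,1,1
65,1,3,1,green,high,pink,1,1
66,1,3,1,red,high,pink,0,1
67,1,3,1,red,low,pink,1,1
68,1,3,1,green,high,pink,1,1
69,1,3,1,green,high,pink,1,1
70,1,4,0,green,low,orange,0,0
71,1,4,0,red,low,orange,1,0
72,1,4,0,red,high,orange,0,0
73,1,4,0,red,high,orange,0,0
74,1,4,0,green,low,orange,0,0
75,1,4,0,red,high,orange,0,0
76,1,4,0,red,high,orange,0,0
77,1,4,0,red,high,orange,0,0
78,1,4,0,red,high,orange,0,0
79,1,4,0,red,low,orange,1,0
80,1,4,0,red,high,orange,0,0
81,2,5,1,green,high,pink,1,1
82,2,5,1,red,low,pink,1,1
83,2,5,1,red,low,pink,1,1
84,2,5,1,green,high,pink,1,1
85,2,5,1,red,high,pink,0,1
86,2,5,1,red,low,pink,1,1
87,2,5,1,red,low,pink,1,1
88,2,5,1,green,high,pink,1,1
89,2,5,1,green,high,pink,1,1
90,2,5,1,green,high,pink,1,1
91,2,5,1,red,low,pink,1,1
92,2,5,1,red,low,pink,1,1
93,2,5,1,red,low,pink,1,1
94,2,5,1,red,low,pink,1,1
95,2,5,1,red,low,pink,1,1
96,2,5,1,red,low,pink,1,1
97,2,5,1,green,low,pink,0,1
98,2,5,1,green,high,pink,1,1
99,2,5,1,green,high,pink,1,1
100,2,5,1,red,low,pink,1,1
101,2,5,1,green,high,pink,1,1
102,2,5,1,red,low,pink,1,1
103,2,5,1,green,high,pink,1,1
104,2,5,1,red,low,pink,1,1
105,2,5,1,green,high,pink,1,1
106,2,6,0,green,low,orange,0,0
107,2,6,0,green,low,orange,0,0
108,2,6,0,red,high,orange,0,0
109,2,6,0,green,high,orange,1,0
110,2,6,0,red,high,orange,0,0
111,2,7,1,red,low,pink,1,1
112,2,7,1,red,low,pink,1,1
113,2,7,1,green,high,pink,1,1
114,2,7,1,red,high,pink,0,1
115,2,7,1,green,high,pink,1,1
116,2,7,1,red,low,pink,1,1
117,2,7,1,green,high,pink,1,1
118,2,7,1,green,high,pink,1,1
119,2,7,1,green,high,pink,1,1
120,2,7,1,red,low,pink,1,1
121,2,7,1,red,low,pink,1,1
122,2,7,1,red,low,pink,1,1
123,2,7,1,green,high,pink,1,1
124,2,7,1,red,low,pink,1,1
125,2,7,1,red,low,pink,1,1
126,2,7,1,green,high,pink,1,1
127,2,7,1,red,low,pink,1,1
128,2,7,1,red,low,pink,1,1
129,2,7,1,red,low,pink,1,1
130,2,7,1,red,low,pink,1,1
131,2,7,1,green,high,pink,1,1
132,2,7,1,red,low,pink,1,1
133,2,7,1,green,high,pink,1,1
134,2,7,1,red,low,pink,1,1
135,2,7,1,green,high,pink,1,1
136,2,7,1,green,high,pink,1,1
137,2,7,1,red,low,pink,1,1
138,2,8,0,green,low,orange,0,0
139,2,8,0,green,low,orange,0,0
140,2,8,0,green,low,orange,0,0
141,2,8,0,green,high,orange,1,0
142,2,8,0,red,high,orange,0,0
143,2,8,0,green,low,orange,0,0
144,2,8,0,red,high,orange,0,0
145,2,8,0,red,low,orange,1,0
146,2,8,0,red,high,orange,0,0
147,2,8,0,red,high,orange,0,0
148,2,8,0,green,low,orange,0,0
149,2,8,0,green,low,orange,0,0
150,2,8,0,green,low,orange,0,0
151,2,8,0,red,high,orange,0,0
152,2,8,0,green,low,orange,0,0
153,2,8,0,red,high,orange,0,0
154,2,8,0,green,low,orange,0,0
155,2,8,0,red,high,orange,0,0
156,2,8,0,green,low,orange,0,0
157,2,8,0,red,high,orange,0,0
158,2,8,0,green,low,orange,0,0
159,2,8,0,green,low,orange,0,0
160,2,9,1,green,low,pink,0,1
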