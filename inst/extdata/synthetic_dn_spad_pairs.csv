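"dn","spad","band"
83.2,33.1,"red"
91.3,32,"red"
126.7,21.6,"red"
82.2,33.7,"red"
127.3,19,"red"
70.6,34.4,"red"
125.6,21.9,"red"
124.2,21.9,"red"
106.4,25.5,"red"
70.7,33.8,"red"
108,26.5,"red"
68.4,34.7,"red"
105.1,26.4,"red"
139.9,18.4,"red"
99.4,25.5,"red"
69.2,34.5,"red"
96.4,29.3,"red"
96.2,25.4,"red"
62.1,34.6,"red"
77.8,33.3,"red"
147.3,14.8,"red"
123,22,"red"
74.1,34.6,"red"
123.2,23.4,"red"
78.9,32.7,"red"
142.7,15.6,"red"
110.5,27.6,"red"
145.2,15.9,"red"
91.6,29.7,"red"
68,37.1,"red"
98.8,28,"red"
141.5,18.5,"red"
82.8,30.1,"red"
103.2,25.9,"red"
120.3,22,"red"
101.7,26.6,"red"
116.7,23.1,"red"
81.8,29.8,"red"
63.9,36.1,"red"
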