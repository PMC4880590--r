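"part","spad"
1,35.8
2,36.5
3,39.2
4,40.3
5,40.6
6,39.8
7,41.2
8,39.4
9,37.1
10,34.3
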