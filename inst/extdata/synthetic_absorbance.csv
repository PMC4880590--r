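"a665","a649","volume_l","mass_g"
0.341,0.168,0.01,0.0224
0.569,0.234,0.01,0.0249
0.464,0.228,0.01,0.0209
0.467,0.211,0.01,0.0177
0.445,0.183,0.01,0.0237
0.331,0.126,0.01,0.0266
0.506,0.18,0.01,0.0165
0.816,0.297,0.01,0.0255
0.39,0.188,0.01,0.02
0.542,0.246,0.01,0.0164
0.819,0.303,0.01,0.0266
0.576,0.217,0.01,0.0241
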