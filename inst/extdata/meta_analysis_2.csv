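pvalue
0.94
0.0015
0.97
0.79
0.81
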