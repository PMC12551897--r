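pvalue
0.78
0.002
0.74
0.016
0.89
0.10
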