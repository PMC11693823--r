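times_participated,n_children
4,4
3,8
2,42
1,312
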