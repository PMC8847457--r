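t0,t1,t2
4,6,5
2,7,9
3,3,8
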