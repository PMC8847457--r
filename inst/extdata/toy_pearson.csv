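x,y
1.0,2.1
2.0,3.9
3.0,6.2
4.0,7.8
5.0,10.3
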