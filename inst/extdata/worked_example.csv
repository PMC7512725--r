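3.6
4.2
1.2
3.1
4.2
2.1
3.3
4.6
6.8
8.4
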