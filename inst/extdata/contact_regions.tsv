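size	count
2	12
3	12
4	13
5	8
6	7
7	5
8	1
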