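spacer	protospacer
101	11
102	12
103	13
104	14
105	15
106	16
107	17
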