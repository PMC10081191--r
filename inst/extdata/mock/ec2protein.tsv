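1.1.1.1	NP_900004.1
1.1.1.2	NP_900004.1
1.1.1.2	NP_900005.1
1.1.1.3	NP_900002.1
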