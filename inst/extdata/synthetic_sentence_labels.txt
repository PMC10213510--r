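0.000000	1.200000	early
1.200000	2.861000	gap
2.861000	3.211000	final
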