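1	20000000
2	15000000
9	5000000
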