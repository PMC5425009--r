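2	8434743	8494298	LMBR1	0	+
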