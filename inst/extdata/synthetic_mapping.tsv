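KIN1	KIN1a,KIN1b	first_pc
TF2	TF2a,TF2b	representative
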