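gene	identifier	POP1
TOYCYP	*1	0.5
TOYCYP	*2	0.3
TOYCYP	*3	0.2
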