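gene	allele	defining_variants	activity_value	function_class	copy_number
TOYCYP	*1		1	normal	1
TOYCYP	*2	rs000002	0	no	1
TOYCYP	*3	rs000003	0	no	1
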