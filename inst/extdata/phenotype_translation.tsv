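gene	function_a	function_b	diplotype	label
CYP3A5	normal	normal		extensive
CYP3A5	decreased	normal		intermediate
CYP3A5	no	normal		intermediate
CYP3A5	decreased	decreased		poor
CYP3A5	decreased	no		poor
CYP3A5	no	no		poor
*	normal	normal		normal
*	decreased	normal		intermediate
*	no	normal		intermediate
*	decreased	decreased		poor
*	decreased	no		poor
*	no	no		poor
*	increased	normal		rapid
*	increased	increased		ultrarapid
*	increased	no		intermediate
*	decreased	increased		likely intermediate
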