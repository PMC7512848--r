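class	count
EBL	165
DBL	13
ENL	7
U	0
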