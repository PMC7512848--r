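class	count
EBL	172
DBL	5
ENL	5
U	0
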