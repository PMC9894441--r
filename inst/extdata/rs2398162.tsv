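genotype	aa	Aa	AA
cases	1205	624	111
controls	1608	1121	194
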