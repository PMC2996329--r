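strain	class	type	count
MH3359	I	INTERNAL_DELETION	5
MH3359	I	ALLELIC	27
MH3359	I	OTHER	0
MH3359	II	ISOCHROMOSOME	11
MH3359	II	RING	1
MH3359	II	TRANSLOCATION	1
MH3359	II	OTHER	1
MH3359	II	ALLELIC	32
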