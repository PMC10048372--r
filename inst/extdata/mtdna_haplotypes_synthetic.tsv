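haplotype	pos	allele
A2	15639	T
A2	15955	A
A2	16025	G
A22	15639	T
A22	15800	C
A22	16431	A
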