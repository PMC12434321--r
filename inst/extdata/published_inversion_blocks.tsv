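chromosome	ld_block_start_mb	ld_block_end_mb	inversion_size_mb
12	14	35	18
19	22	39	12
27	13	35	12
31	15	40	26
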