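study	items	n11	n10	n01	n00	universe_size
midbrain_vectors	components	32	23	12	1833	1907
midbrain_genes	genes	305	151	200	13233	13889
hypothalamus_vectors	components	23	7	1	1065	1096
hypothalamus_genes	genes	3324	826	297	19894	24341
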