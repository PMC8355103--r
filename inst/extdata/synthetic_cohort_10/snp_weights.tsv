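snp_id	weight
snp_001	0.105258240199184
snp_002	-0.113634283759831
snp_003	-0.0772232840226462
snp_004	0.0795036245170561
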