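sample_id	snp_001	snp_002	snp_003	snp_004
S0001	0	1	2	2
S0002	1	0	2	1
S0003	0	1	0	1
S0004	0	1	2	1
S0005	1	0	1	0
S0006	1	0	2	0
S0007	0	0	1	0
S0008	0	1	1	0
S0009	0	0	0	0
S0010	0	2	1	0
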