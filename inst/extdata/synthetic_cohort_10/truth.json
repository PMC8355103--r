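{"truth":{"informative":["let-7g-5p","miR-21-5p"],"effects":{"let-7g-5p":0.6,"miR-21-5p":-0.5},"snp_log_or":{"snp_001":0.105258240199184,"snp_002":-0.113634283759831,"snp_003":-0.0772232840226462,"snp_004":0.0795036245170561},"snp_freqs":{"snp_001":0.163980279408861,"snp_002":0.161612567049451,"snp_003":0.460935615352355,"snp_004":0.235344439197797},"hemolyzed":"S0008","time_to_dx_years":{"S0001":"NA","S0002":"NA","S0003":"NA","S0004":1.46755437506363,"S0005":"NA","S0006":7.14304759027436,"S0007":"NA","S0008":6.24408407881856,"S0009":5.5871923295781,"S0010":10.8308630981483},"seed":20260919},"config":{"n_cases":5,"n_controls":5,"n_candidate_mirnas":8,"n_informative":2,"effect_sizes":[0.6,-0.5],"informative_names":["let-7g-5p","miR-21-5p"],"assay_noise_sd":1,"normalizer_names":["miR-93-5p","miR-1246","miR-223-3p"],"normalizer_sd":0.15,"spikein_means":{"UniSp2":21.26,"UniSp4":28.42,"UniSp6":18.15},"spikein_sds":{"UniSp2":1.93,"UniSp4":2.82,"UniSp6":0.11},"hemolysis_fraction":0.1,"missing_fraction":0,"missing_mechanism":"mcar","n_snps":4,"snp_freqs":null,"snp_log_or":null,"covariate_effects":{"age":0.02,"sex":0.35,"family_history":0.45,"bmi":0.02,"pack_years":0.01},"seed":20260919}}
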