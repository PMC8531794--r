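axis	stratum	model	or	ci_low	ci_high	p	i2	known_inconsistency
cancer_group	digestive	recessive	1.16	1.02	1.31	0.025	NA	FALSE
cancer_group	digestive	homozygous	1.21	1.04	1.41	0.014	NA	FALSE
cancer_group	urinary	homozygous	1.39	1.04	1.87	0.025	NA	FALSE
cancer_group	breast	homozygous	1.56	1.03	2.35	0.034	NA	FALSE
cancer_group	breast	recessive	1.60	1.08	2.38	0.020	36.2	FALSE
cancer_group	lung	homozygous	0.70	0.53	0.92	0.010	NA	FALSE
ethnicity	European	homozygous	1.15	0.89	1.48	0.296	NA	FALSE
ethnicity	East Asian	homozygous	0.71	0.47	1.08	0.109	NA	FALSE
ethnicity	West Asian	homozygous	1.05	0.65	1.68	0.845	NA	FALSE
size_class	small	dominant	0.85	0.74	0.98	0.026	NA	FALSE
size_class	large	heterozygous	1.26	1.10	1.45	0.001	NA	TRUE
control_source	HB	recessive	1.47	1.04	2.09	0.030	NA	FALSE
control_source	PB	recessive	1.12	0.96	1.30	0.162	NA	FALSE
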