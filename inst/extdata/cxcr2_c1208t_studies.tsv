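author	year	origin	cancer_type	ethnicity	control_source	genotyping_method	case_tt	case_tc	case_cc	control_tt	control_tc	control_cc	age_case	age_control	hwe_case	hwe_control
Kamangar	2006	Finland	GC	European	PB	TaqMan	36	61	15	66	108	34	Mean 58.5	59 (50-69)	0.172	0.359
Brown	2006	Italy	KS	European	PB	TaqMan	14	40	79	16	69	87	72 (29-91)	75 (37-92)	0.016	0.666
Lee	2007	China	LC	East Asian	PB	PCR	55	47	13	44	51	12	NA	NA	0.542	0.628
Sarvestani	2007	Iran	BC	West Asian	HB	PCR	27	85	106	27	114	120	49.4 (28-85)	NA	0.131	0.992
Andrew	2009	USA	BLCA	European	PB	GoldenGate	250	255	84	299	414	150	64 (25-74)	NA	0.149	0.745
Snoussi	2010	Tunisia	BC	African	HB	PCR	47	167	195	18	128	155	48.0 +/- 24.0	48.0 +/- 14.9	0.222	0.207
Bondurant	2013	USA	CC	European	PB	GoldenGate	343	794	417	411	1009	536	30-79	NA	0.340	0.112
Bondurant	2013	USA	RC	European	PB	GoldenGate	201	359	192	199	470	290	30-79	NA	0.216	0.736
Singh	2014	India	BLCA	West Asian	HB	PCR	15	73	112	14	90	96	58.5 +/- 12.4	56.8 +/- 10.8	0.520	0.247
Ryan	2015	USA	LC	European	PB	iPlexGold	90	215	138	115	238	121	66.6 +/- 10.0	67.4 +/- 8.5	0.708	0.924
Ryan	2015	Japan	LC	East Asian	PB	TaqMan	170	160	54	178	170	35	59.0 +/- 8.0	59.0 +/- 8.0	0.104	0.537
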