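subject_id	cohort	germline_variants	germline_classification	other_germline	personal_history	parent_of_origin	family_history	multifocal	metastasis	somatic_alterations	kit_status	pdgfra_status	ihc_sdha	ihc_sdhb	diagnoses
6	GERMLINE_AND_TUMOR	SDHA:c.853C>T (p.Leu285Phe)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
9	GERMLINE_AND_TUMOR	SDHA:c.1216G>A (p.Val406Met)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
17	GERMLINE_AND_TUMOR	SDHB:c.170A>G (p.His57Arg)	VUS	SDHA:c.-4A; RET:c.405C>T (p.Gly135=)	Yes	NT	Neg	Neg	Neg	Neg	WT	WT	NT	Intact
21	GERMLINE_AND_TUMOR	SDHA:c.1894G>T (p.Val632Phe)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
24	GERMLINE_AND_TUMOR	SDHA:c.1523C>T (p.Thr508Ile)	VUS	Neg	Yes	NT	Neg	Neg	Yes, PGL metastasis	Neg	WT	WT	NT	Intact
31	GERMLINE_AND_TUMOR	SDHA:c.596C>T (p.Ser199Leu)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
34	GERMLINE_AND_TUMOR	SDHA:c.287C>T (p.Thr96Ile)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
39	GERMLINE_AND_TUMOR	SDHA:c.133G>A (p.Ala45Thr)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
41	GERMLINE_AND_TUMOR	SDHA:c.872A>T (p.Glu291Val)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
44	GERMLINE_AND_TUMOR	SDHA:c.955A>C (p.Ile319Leu)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
45	GERMLINE_AND_TUMOR	SDHA:c.1006G>T (p.Asp336Tyr)	VUS	Neg	Yes (+GIST)	NT	Neg	Neg	Neg	SDHA:c.511C>T (p.Arg171Cys)	WT	WT	Intact	Intact
47	GERMLINE_AND_TUMOR	SDHA:c.1908+6T>C	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
48	GERMLINE_AND_TUMOR	SDHA:c.464A>G (p.Asn155Ser)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
49	GERMLINE_AND_TUMOR	SDHA:c.1472A>C (p.Glu491Ala)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	c.1091A>G	WT	NT	NT
50	GERMLINE_AND_TUMOR	SDHA:c.530G>C (p.Ser177Thr)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
55	GERMLINE_AND_TUMOR	SDHA:c.737G>A (p.Arg246His)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
56	GERMLINE_AND_TUMOR	SDHA:c.830C>T (p.Thr277Met)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
57	GERMLINE_AND_TUMOR	SDHA:c.464A>G (p.Asn155Ser)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
62	GERMLINE_AND_TUMOR	SDHA:c.1064+5G>A	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
65	GERMLINE_AND_TUMOR	SDHA:c.1064+5G>A	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
66	GERMLINE_AND_TUMOR	SDHA:c.1325C>T (p.Ala442Val)	VUS	Neg	Yes	NT	Neg	Neg	Neg	Neg	WT	WT	NT	Loss
67	GERMLINE_AND_TUMOR	SDHA:c.955A>C (p.Ile319Leu)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
68	GERMLINE_AND_TUMOR	SDHA:c.1115C>G (p.Pro372Arg)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
70	GERMLINE_AND_TUMOR	SDHA:c.1340A>G (p.His447Arg)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
74	GERMLINE_AND_TUMOR	SDHA:c.1648A>C (p.Lys550Gln)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
75	GERMLINE_AND_TUMOR	SDHA:c.1763C>T (p.Ser588Leu)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
81	GERMLINE_AND_TUMOR	SDHA:c.872A>T (p.Glu291Val)	VUS	SDHC:c.54T>G (p.Phe18Leu)	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
84	GERMLINE_AND_TUMOR	SDHA:c.1835G>A (p.Gly612Glu)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
85	GERMLINE_AND_TUMOR	SDHA:c.499A>C (p.Lys167Gln)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
86	GERMLINE_AND_TUMOR	SDHA:c.613T>C (p.Tyr205His)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
88	GERMLINE_AND_TUMOR	SDHA:c.737G>A (p.Arg246His)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
89	GERMLINE_AND_TUMOR	SDHA:c.287C>T (p.Thr96Ile)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
90	GERMLINE_AND_TUMOR	SDHA:c.391G>A (p.Asp131Asn)	VUS	Neg	No	NT	Neg	Neg	Neg	SDHA Copy Number Gain (6n)	WT	WT	NT	NT
91	GERMLINE_AND_TUMOR	SDHA:c.1429C>T (p.Pro477Ser)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
95	GERMLINE_AND_TUMOR	SDHA:c.1115C>G (p.Pro372Arg)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
96	GERMLINE_AND_TUMOR	SDHA:c.830C>T (p.Thr277Met)	VUS	SDHB:c.523G>A (p.Glu175Lys)	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
99	GERMLINE_AND_TUMOR	SDHA:c.935G>T (p.Arg312Leu)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
100	GERMLINE_AND_TUMOR	SDHA:c.830C>T (p.Thr277Met)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
101	GERMLINE_AND_TUMOR	SDHA:c.1908+6T>C	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
105	GERMLINE_AND_TUMOR	SDHA:c.724G>A (p.Gly242Arg)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	c.369C>G	NT	NT
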