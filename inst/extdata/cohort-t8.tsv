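subject_id	cohort	germline_variants	germline_classification	other_germline	personal_history	parent_of_origin	family_history	multifocal	metastasis	somatic_alterations	kit_status	pdgfra_status	ihc_sdha	ihc_sdhb	diagnoses
29	GERMLINE_AND_TUMOR	SDHD:c.453A>C (p.Lys151Asn)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
40	GERMLINE_AND_TUMOR	SDHD:c.400T>G (p.L134V)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
42	GERMLINE_AND_TUMOR	SDHD:c.53C>T (p.Ala18Val)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
73	GERMLINE_AND_TUMOR	SDHD:c.80G>A (p.Arg27Lys)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
76	GERMLINE_AND_TUMOR	SDHD:c.101T>G (p.Phe34Cys)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
98	GERMLINE_AND_TUMOR	SDHD:c.53C>T (p.A18V)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
108	GERMLINE_AND_TUMOR	SDHD:c.428A>G (p.Asn143Ser)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
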