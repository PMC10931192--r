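subject_id	cohort	germline_variants	germline_classification	other_germline	personal_history	parent_of_origin	family_history	multifocal	metastasis	somatic_alterations	kit_status	pdgfra_status	ihc_sdha	ihc_sdhb	diagnoses
16	GERMLINE_AND_TUMOR	SDHC:c.20+6T>G	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
52	GERMLINE_AND_TUMOR	SDHC:c.476C>T (p.Thr159Ile)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
64	GERMLINE_AND_TUMOR	SDHC:c.292T>G (p.Ser98Ala)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
77	GERMLINE_AND_TUMOR	SDHC:c.292T>G (p.Ser98Ala)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
87	GERMLINE_AND_TUMOR	SDHC:c.103A>G (p.Lys35Glu)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
94	GERMLINE_AND_TUMOR	SDHC:c.15G>T (p.Leu5Phe)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
102	GERMLINE_AND_TUMOR	SDHC:c.40C>T (p.Leu14Phe)	VUS	Neg	No	NT	Neg	Neg	Neg	SDHC Gain	WT	WT	NT	NT
103	GERMLINE_AND_TUMOR	SDHC:c.20+20G>T	VUS	Neg	No	NT	Neg	Neg	Neg	SDHC Gain (estimated 6 copies)	WT	WT	NT	NT
104	GERMLINE_AND_TUMOR	SDHC:c.32G>T (p.Arg11Leu)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
106	GERMLINE_AND_TUMOR	SDHC:c.-30-?_2318+?dup	VUS	Neg	No	NT	Neg	Neg	Neg	SDHC Gain (estimated 8 copies)	WT	WT	NT	NT
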