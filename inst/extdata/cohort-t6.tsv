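subject_id	cohort	germline_variants	germline_classification	other_germline	personal_history	parent_of_origin	family_history	multifocal	metastasis	somatic_alterations	kit_status	pdgfra_status	ihc_sdha	ihc_sdhb	diagnoses
3	GERMLINE_AND_TUMOR	SDHB:159_184delIns25 (p.Gly53fs)	VUS	Neg	Yes (+GIST)	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT	PGL; GIST
4	GERMLINE_AND_TUMOR	SDHB:c.72+3G>A	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
10	GERMLINE_AND_TUMOR	SDHB:c.158G>A (p.Gly53Glu)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
19	GERMLINE_AND_TUMOR	SDHB:c.487T>C (p.Ser163Pro)	VUS	Neg	No	NT	Neg	Neg	Neg	SDHB One Copy Deletion	WT	WT	NT	Intact	RCC
25	GERMLINE_AND_TUMOR	SDHB:c.478_480del (p.Lys160del)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
26	GERMLINE_AND_TUMOR	SDHB:c.553G>A (p.Glu185Lys)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
27	GERMLINE_AND_TUMOR	SDHB Duplication	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
36	GERMLINE_AND_TUMOR	SDHB:c.687G>C (p.Glu229Asp)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
58	GERMLINE_AND_TUMOR	SDHB:c.79C>G (p.Arg27Gly)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
69	GERMLINE_AND_TUMOR	SDHB:c.329C>T (p.Thr110Ile)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
71	GERMLINE_AND_TUMOR	SDHB:c.317A>G (p.Asn106Ser)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
78	GERMLINE_AND_TUMOR	SDHB:c.67C>G (p.Leu23Val)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
83	GERMLINE_AND_TUMOR	SDHB:c.478_480del (p.Lys160del)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
97	GERMLINE_AND_TUMOR	SDHB:c.529C>A (p.Arg177Ser)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
109	GERMLINE_AND_TUMOR	SDHB:c.178A>G (p.Thr60Ala)	VUS	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
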