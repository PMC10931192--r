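subject_id	cohort	germline_variants	germline_classification	other_germline	personal_history	parent_of_origin	family_history	multifocal	metastasis	somatic_alterations	kit_status	pdgfra_status	ihc_sdha	ihc_sdhb	diagnoses
1	GERMLINE_AND_TUMOR	SDHC:c.397C>T (p.Arg133Ter)	P	Neg	No (GIST)	NT	Neg	Neg	Neg	Neg	WT	WT	Intact	NT
2	GERMLINE_AND_TUMOR	SDHA:c.615T>A (p.Tyr205Ter)	P	Neg	No (GIST)	NT	Neg	Neg	Neg	Neg	WT	WT	Loss	Loss
5	GERMLINE_AND_TUMOR	SDHB:c.380T>G (p.Ile127Ser)	P	Neg	No (GIST)	NT	Yes, PGL in mother	Neg	Neg	Neg	WT	WT	NT	NT
7	GERMLINE_AND_TUMOR	SDHA:c.1753C>T (p.Arg585Trp)	P	Neg	Yes	NT	Neg	Neg	Yes, PGL metastasis	SDHA:c.1534C>T (p.Arg512Ter); SDHA:c.1091T>C (p.Val364Ala)	WT	WT	Equivocal	Loss
8	GERMLINE_AND_TUMOR	SDHB:c.600G>T (p.Trp200Cys)	P	Neg	No (GIST)	NT	Neg	Neg	Neg	Neg	WT	WT	NT	Loss
11	GERMLINE_AND_TUMOR	SDHC:c.224G>A (p.Gly75Asp)	P	Neg	No (GIST)	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
12	GERMLINE_AND_TUMOR	SDHA:c.91C>T (p.Arg31Ter)	P	Neg	No (GIST)	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
13	GERMLINE_AND_TUMOR	SDHC:c.43C>T (p.Arg15Ter)	P	Neg	Yes	NT	Neg	Neg	Neg	Neg	WT	WT	Intact	Loss
14	GERMLINE_AND_TUMOR	SDHB:c.380T>G (p.Ile127Ser)	P	Neg	Yes	NT	Neg	Neg	Neg	SDHB One Copy Deletion	WT	WT	NT	NT
15	GERMLINE_AND_TUMOR	SDHC:c.397C>T (p.Arg133Ter)	P	Neg	No (GIST)	NT	Neg	Neg	Neg	Neg	WT	WT	NT	Loss
18	GERMLINE_AND_TUMOR	SDHB:c.605_609dupACGGA (p.Asp204fs)	P	Neg	No	NT	Yes, PGL in son	Neg	Neg	SDHB One Copy Deletion	WT	WT	NT	NT
20	GERMLINE_AND_TUMOR	SDHC:c.223G>C (p.Gly75Arg)	P	Neg	Yes	NT	Neg	Neg	Neg	Neg	WT	WT	Intact	Intact
22	GERMLINE_AND_TUMOR	SDHC:c.397C>T (p.Arg133Ter)	P	Neg	Yes	NT	Neg	Neg	Neg	Neg	WT	WT	NT	Loss
23	GERMLINE_AND_TUMOR	SDHC:c.397C>T (p.Arg133Ter)	P	Neg	No	NT	Yes, PGL in Father	Neg	Neg	Neg	WT	WT	Intact	Intact
28	GERMLINE_AND_TUMOR	SDHB:c.72+1G>T	P	Neg	Yes	NT	Neg	Neg	Neg	SDHB One Copy Deletion	WT	WT	NT	Loss
30	GERMLINE_AND_TUMOR	SDHB:c.194T>A (p.Leu65His)	P	SDHB:c.200+3G>C	Yes	NT	Neg	Neg	Yes, PGL metastasis	Neg	WT	WT	NT	Loss
32	GERMLINE_AND_TUMOR	SDHB:c.137G>A (p.Arg46Gln)	P	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
33	GERMLINE_AND_TUMOR	SDHB:c.137G>A (p.Arg46Gln)	P	Neg	Yes	NT	Neg	Neg	Neg	SDHB One Copy Deletion	WT	WT	Intact	Loss
35	GERMLINE_AND_TUMOR	SDHC:c.397C>T (p.Arg133Ter)	P	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	Intact
37	GERMLINE_AND_TUMOR	SDHB EX8_3'UTR Del	P	Neg	Yes	NT	Neg	Neg	Neg	SDHB One Copy Deletion	WT	WT	NT	Intact
38	GERMLINE_AND_TUMOR	SDHA:c.91C>T (p.Arg31Ter)	P	Neg	No (GIST)	NT	Neg	Neg	Neg	SDHA One Copy Deletion	WT	WT	NT	NT
43	GERMLINE_AND_TUMOR	SDHC:c.397C>T (p.Arg133Ter)	P	Neg	Yes	NT	Neg	Neg	Neg	Neg	WT	WT	NT	Intact
46	GERMLINE_AND_TUMOR	SDHC:c.397C>T (p.Arg133Ter)	P	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
51	GERMLINE_AND_TUMOR	SDHA EX1_9 Del	P	Neg	No (GIST)	NT	Neg	Neg	Neg	SDHA One Copy Deletion	WT	WT	Loss	Loss
53	GERMLINE_AND_TUMOR	SDHC EX6 Del	P	RET:c.1771G>A	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
54	GERMLINE_AND_TUMOR	SDHA:c.1794+1G>A	P	SDHA:c.1246A>G (p.Asn416Asp)	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
59	GERMLINE_AND_TUMOR	SDHC:c.43C>T (p.Arg15Ter)	P	Neg	Yes	NT	Neg	Neg	Neg	Neg	WT	WT	NT	Loss
60	GERMLINE_AND_TUMOR	SDHA:c.563G>A (p.Arg188Gln)	P	Neg	No	NT	Neg	Neg	Neg	SDHA Copy Number Gain (<6 copies)	WT	WT	NT	NT
61	GERMLINE_AND_TUMOR	SDHA:c.688delG (p.Glu230fs)	P	Neg	Yes (+GIST)	NT	Neg	Neg	Neg	SDHA:c.1432+1G>C	WT	WT	Loss	Loss
63	GERMLINE_AND_TUMOR	SDHB:c.487T>C (p.Ser163Pro)	P	SDHA:c.553C>T (p.Gln185Ter); SDHA:c.622-7C>T	Yes (+GIST)	NT	Neg	Neg	Neg	SDHB One Copy Deletion; SDHA:c.1043_1055del (p.Thr348LysfsTer37)	WT	WT	NT	Loss
72	GERMLINE_AND_TUMOR	SDHA:c.91C>T (p.Arg31Ter)	P	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
79	GERMLINE_AND_TUMOR	SDHA:c.91C>T (p.Arg31Ter)	P	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
80	GERMLINE_AND_TUMOR	SDHB Ex1 Del	P	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	Loss
82	GERMLINE_AND_TUMOR	SDHB:c.137G>A (p.Arg46Gln)	P	Neg	Yes (+GIST)	NT	Yes, PGL in Brother	Yes	Yes, PGL metastasis	SDHB One Copy Deletion	WT	WT	NT	Loss
92	GERMLINE_AND_TUMOR	SDHC:c.397C>T (p.Arg133Ter)	P	Neg	No	NT	Neg	Neg	Neg	Neg	WT	WT	NT	NT
93	GERMLINE_AND_TUMOR	SDHD:c.106C>T (p.Gln36Ter)	P	Neg	Yes	Paternal	Yes, PGL in Father	Neg	Neg	SDHD One Copy Deletion	WT	WT	NT	Loss
107	GERMLINE_AND_TUMOR	SDHB:c.418G>T (p.Val140Phe)	P	Neg	Yes	NT	Neg	Neg	Yes, PGL metastasis	SDHB One Copy Deletion	WT	WT	NT	Loss
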