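---
title: "Integrated germline and tumor evidence assessment for HPPGL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated germline and tumor evidence assessment for HPPGL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hppglintegrate)
```

## The problem

Hereditary paraganglioma–pheochromocytoma syndromes (HPPGL) are caused by
heterozygous germline pathogenic variants in the SDHx genes (*SDHA*, *SDHB*,
*SDHC*, *SDHD*), which encode the four subunits of succinate dehydrogenase
and act as tumor suppressors. Standard germline classification struggles
here for two reasons: many SDHx variants surface as incidental findings on
large panels, and sporadic SDH-deficient tumors can mimic the constitutional
phenotype. Tumor-derived evidence resolves much of this ambiguity — under
the two-hit model a relevant germline allele should be accompanied by a
somatic inactivating allele in the *same* gene, and biallelic SDHx
inactivation produces characteristic immunohistochemistry (IHC) patterns:
loss of any subunit ablates SDHB staining, while SDHA staining is lost
specifically with *SDHA* inactivation. SDH-deficient GISTs are additionally
wild-type for *KIT* and *PDGFRA*, the usual drivers of sporadic GIST.

`hppglintegrate` implements a rule-based engine that combines four evidence
families for one germline SDHx variant at a time — germline variant status,
clinical genetics history, tumor-derived genomics, and SDHA/SDHB IHC — into
a framework category (`POSITIVE`, `NEUTRAL`, `NEGATIVE`) with a
standardized, verbatim scenario comment. It is deliberately *not* an ACMG
classifier and never reclassifies a variant: it is an evidence-collation
companion whose output is designed for public sharing (a ClinVar-style
submission payload carrying the evidence in its comment field).

## The evidence vector and the decision table

Every assessment consults exactly eleven columns, housed in
`evidence_vector()`: the gene plus ten tri-state/enumerated parameters
(additional qualifying germline variant; personal history of PGL/PCC with or
without associated GIST; paternal inheritance, consulted only for *SDHD*
because of its parent-of-origin effect; family history; multifocal or
extra-adrenal tumors; metastasis; same-gene somatic inactivating allele;
combined KIT/PDGFRA status; SDHA stain; SDHB stain). `"NA"` always means
*not ascertained*, never negative — a column absent from an input file stays
`NA`.

The decision table ships as data
(`system.file("extdata", "rulebook.tsv", package = "hppglintegrate")`): 19
scenarios — 5 each for *SDHA*, *SDHB*, *SDHD* and 4 for *SDHC* — each a set
of allowed values per column plus a category and comment. Matching is
gene-scoped table-order evaluation; because mutual exclusivity is
machine-verified (below), order never affects the result. Two outcomes sit
outside the table: a vector carrying an additional qualifying germline
variant (a second SDHx variant, or any variant in *SDHAF2*, *MAX*,
*TMEM127*, *EPAS1*, *VHL*, *RET*, *NF1*) is disqualified outright, since the
framework assesses one informative variant at a time; and any unmatched
combination returns a `NOT_ACCOUNTED` fallback rather than forcing a
category.

```{r}
rb <- load_rulebook()
res <- match_rule(rb, evidence_vector(
  "SDHB", additional_hppgl_germline = "NO", personal_history = "YES",
  family_history = "YES", multifocal = "YES", metastasis = "YES",
  somatic_inactivating = "YES", kit_pdgfra = "WT",
  ihc_sdha = "INTACT", ihc_sdhb = "LOSS"))
res$matched_code
res$category
```

### Strict and lenient matching

The printed decision table is conservative in a way that interacts awkwardly
with fully worked-up negative ancillary findings: several family-history,
multifocality and metastasis cells list only "Yes, N/A", so a patient whose
family history was ascertained and *negative* would match nothing even when
every required parameter is positive. The engine therefore supports two
modes:

* **STRICT** matches the encoded cells literally.
* **LENIENT** (default) adds two relaxations: (a) family-history,
  multifocal and metastasis cells that do not list "No" additionally accept
  it — a documented negative ancillary finding is never treated as worse
  than an unascertained one; (b) for genes other than *SDHA*, a "Normal"
  SDHA-stain requirement additionally accepts a not-performed SDHA stain,
  because only SDHB loss is informative for those genes and SDHA staining is
  typically reflexive.

On the packaged 37-record pathogenic reference cohort, strict matching
yields no `POSITIVE` call at all, while lenient matching yields six
(subjects 28, 33, 61, 82, 93 and 107). The reference narrative singles out
three fully concordant cases (33, 61, 82); no literal reading of the printed
table reproduces exactly that set, so we record the claim as
non-reproducible rather than tuning cells to force it — the lenient result
is a strict superset, which is the closest behavior derivable from the
table as printed.

### Machine-verified integrity

The evidence space is finite (3^7 × 3 × 4 × 4 = 104,976 vectors per gene),
so the two properties the matcher relies on are checked by exhaustive
enumeration rather than argued: `check_exclusivity()` confirms no vector
matches two rules (in both modes), and `enumerate_reachable()` confirms
every scenario has at least one satisfying vector. Both run in seconds and
are part of the test suite.

## Variant nomenclature and the second hit

Clinical report tables mix HGVS strings (`SDHB:c.137G>A (p.Arg46Gln)`) with
copy-number phrases (`SDHB One Copy Deletion`, `SDHA Copy Number Gain
(<6 copies)`), exon-level deletions (`SDHA EX1_9 Del`) and whole-gene
duplications. `parse_variant_string()` handles this dialect totally —
unparseable input yields a failure descriptor, never an error — and
`consequence_class()` maps the notation deterministically: `fs` suffixes to
frameshift, terminal `Ter` to nonsense, intronic offsets of ±1/±2 to
canonical splice disruption (deeper offsets are non-disruptive), single
residue substitutions to missense.

A somatic alteration is an **inactivating allele** (a second hit) when its
consequence is nonsense, frameshift, canonical splice disruption, one-copy
loss, exon-level deletion or a disruptive structural variant. Missense,
synonymous and deep-intronic changes never count, and copy-number gains are
deliberately a third state: neither a second hit nor "negative for somatic
alteration". This three-way split is what makes the reference cohort's
arithmetic close: 13 second hits (11 copy-loss + 2 SNV) + 1 copy gain + 23
negatives = 37 records. The hit is gene-scoped — an inactivating somatic
*SDHA* frameshift is not a second hit for a germline *SDHB* variant.

Whole-gene duplications with uncertain breakpoints (`c.-30-?_2318+?dup`)
are treated as non-inactivating: whether such an event is disruptive cannot
be determined from the notation, and the conservative reading keeps a
potentially intact extra copy from counting as loss.

## Cohort pipeline and summaries

`read_cohort_table()` ingests tab-delimited cohort tables (one row per
subject) in the report dialect; `merge_isgd()` joins germline-side,
tumor-side and clinical sources by subject id into an integrated database,
partitioning subjects into germline+tumor, germline-only and tumor-only
cohorts and reporting (never silently resolving) field conflicts.
`classify_batch()` derives one evidence vector per assessable germline SDHx
variant, matches it, and emits a knowledgebase row plus a structured log
line; records with multiple assessable variants produce one row per variant,
each disqualified as `ADDITIONAL_GERMLINE` (the conservative reading).

`summarize_cohort()` computes the counts used throughout: P/LP records,
positive personal history (positive only for PGL/PCC — an isolated GIST is
carried as a flag but does not count), family history, second hits split by
kind, records with no somatic alteration, and gene-concordant IHC among
second-hit cases. IHC concordance is defined as: germline *SDHA* requires
loss of both stains; germline *SDHB*/*SDHC*/*SDHD* requires SDHB loss with
SDHA not lost; an equivocal or not-performed required stain is
non-concordant. Percentages are reported as `round(100 * k / n)` next to
the raw fraction — the fraction is authoritative.

```{r}
summarize_cohort(load_fixture("T4"))
```

## Submission payloads and the PHI guard

`build_submission()` conforms a knowledgebase row to the packaged JSON
schema (`submission-schema.json`), modeled on the public ClinVar API layout:
variant set by HGVS expression, condition set by the fixed syndrome name, an
`observedIn` block, and an evidence block carrying the framework code,
category, verbatim comment and a templated evidence summary. Payloads never
assert a clinical significance. Copy-number and exon-level germline events,
which have no `c.` expression, are submitted under their descriptive label.

Privacy is enforced structurally and verified dynamically: subject
identifiers, dates and free-text diagnoses are never copied into a payload,
and `phi_scan()` re-scans every record-derived string field for the source
record's identifier and diagnosis strings as whole tokens (so a numeric id
like "7" does not false-alarm against coordinates inside an HGVS string,
but a genuine leak anywhere in free text is caught). The submitter block —
fixed run configuration such as the rulebook version tag — is excluded from
the scan, since record content cannot reach it. `submit_batch()` injects a
transport function; the default dry-run transport serializes documents to
disk, and transport failures are logged per payload without aborting the
loop. Live network submission is intentionally out of scope.

## The synthetic-cohort generator

The packaged fixtures cover only the fully integrated cohort; the raw
records of the germline-only and tumor-only cohorts are not published. The
generator (`synthetic_cohort_params()`, `generate_cohort()`) therefore
emulates the three-cohort structure for scale testing and statistical
validation. Its defaults were fixed once, from the published material:
cohort sizes 109/494/7997 (down-scalable via `scale`); the germline gene
mix of the 109 integrated records (49 *SDHA*, 29 *SDHB*, 23 *SDHC*, 8
*SDHD*); P/LP fraction 37/109; and class-conditional rates equal to the
reference cohort's empirical fractions — personal history 16/37 (P/LP) and
5/72 (VUS), family history 5/37, second hit 13/37 and 1/72, copy-loss split
11/13, gene-concordant IHC 8/13 given a hit, incidental copy gain 1/37,
KIT/PDGFRA mutation 2/109, additional germline variant 7/109. One reported
summary figure (a family-history prevalence printed as "0.03%") is
arithmetically inconsistent with the corresponding count table; the
generator follows counts, not printed percentages.

Conditional independence is assumed wherever the source material provides
no dependence structure (family history, multifocality and metastasis are
drawn independently given the germline class), GIST flags and diagnosis
text are not modeled, and variant strings are synthesized from templates
(nonsense for P/LP, missense for VUS, splice or copy-loss for hits). A
passing recovery test therefore shows that the pipeline preserves marginal
rates at scale — not that the generator reproduces the correlation
structure of real clinical cohorts.

`expected_counts()` provides the closed-form expectations (linearity of
expectation over the stated probabilities) used as the generator's oracle;
at n = 37 with a purely pathogenic cohort the expectations equal the
reference counts by construction. The statistical acceptance check draws
5,000 integrated-cohort records under a fixed seed and requires every
empirical rate to fall within three binomial standard errors of its
parameter; with six monitored rates, a draw exceeding 3 sigma on one of
them has probability about 1.6%, which is why the check pins the seed
rather than averaging over runs.

## Numerical and design choices

* **Problem sizes.** The test suite enumerates the full 104,976-vector
  evidence space per gene for both matching modes and draws 5,000 synthetic
  records for the recovery check; the whole suite runs in well under a
  minute on one core.
* **Determinism.** All generation flows through a single mandatory seed,
  drawn under a private RNG stream that restores the caller's state.
  Classification is a pure function of (rulebook, mode, evidence);
  re-matching stored evidence snapshots byte-reproduces the codes, and
  input order never affects results.
* **Degenerate inputs.** Empty cohort tables yield empty record lists and
  all-zero summaries; records without an assessable SDHx germline variant
  are logged and skipped, never fatal; unparseable variant strings surface
  as validation violations.
* **Ties and precedence.** None exist by construction: exclusivity is
  enumerated, and the matcher treats a double match as an internal error
  rather than resolving it by order.
* **Equivocal IHC** is carried as its own vocabulary value and satisfies no
  stain requirement in either mode — an equivocal stain is non-informative,
  which keeps it from silently upgrading or downgrading a scenario.

## Limitations

The engine assesses exactly the evidence the framework defines: no
epigenetic silencing (e.g. *SDHC* promoter methylation), no cryptic
structural rearrangements, no penetrance modeling, no transcript-aware HGVS
validation, and no support for genes outside the four SDHx subunits. The
table's printed asymmetries (e.g. a metastasis cell reading "N/A" for one
gene and "Any" for another, and the missing IHC-not-performed NEGATIVE
scenario for *SDHC*) are preserved as encoded, not harmonized — the
rulebook is data, and an amended encoding can be loaded without touching
code.
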