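# hppglintegrate

Integrated germline and tumor evidence assessment for hereditary
paraganglioma–pheochromocytoma syndromes (HPPGL).

Heterozygous germline pathogenic variants in the SDHx genes (*SDHA*,
*SDHB*, *SDHC*, *SDHD*) cause HPPGL. Because these genes are tumor
suppressors, the tumor itself carries decisive evidence about a germline
variant's relevance: under the two-hit model a relevant allele should be
accompanied by a **same-gene somatic inactivating allele** (one-copy loss,
nonsense/frameshift, canonical ±1,2 splice disruption, exon deletion or
disruptive structural variant); biallelic SDHx inactivation ablates **SDHB
immunohistochemistry staining** (with SDHA staining lost specifically for
*SDHA*); and SDH-deficient GISTs are **KIT/PDGFRA wild-type**. This package
implements a rule-based engine — a 19-scenario decision table over an
11-column evidence vector (gene; additional qualifying germline variant;
personal history of PGL/PCC ± GIST; paternal inheritance for *SDHD*; family
history; multifocality; metastasis; somatic inactivating allele; KIT/PDGFRA
status; SDHA and SDHB stains) — that returns a framework category
(`POSITIVE` / `NEUTRAL` / `NEGATIVE`, or a `NOT_ACCOUNTED` fallback) with a
standardized verbatim comment. It is an evidence-collation companion for
clinical genetics professionals and variant curators, not an ACMG
classifier: it never reclassifies a variant.

Around the engine sit: a parser for the clinical variant-string dialect and
the inactivating-allele (second hit) determination; a batch cohort pipeline
(tab-delimited tables in, knowledgebase + log out) with an integrated
germline/tumor/clinical merge and cohort summaries; ClinVar-style
submission payload generation with schema validation and a PHI guard;
packaged reference cohort fixtures; and a seeded synthetic-cohort
generator.

## Worked example

Classify a single evidence combination:

```r
library(hppglintegrate)
rb <- load_rulebook()          # 19 scenarios, LENIENT mode by default
res <- match_rule(rb, evidence_vector(
  "SDHB", additional_hppgl_germline = "NO", personal_history = "YES",
  family_history = "YES", multifocal = "YES", metastasis = "YES",
  somatic_inactivating = "YES", kit_pdgfra = "WT",
  ihc_sdha = "INTACT", ihc_sdhb = "LOSS"))
res$matched_code   # "B-I"
res$category       # "POSITIVE"
```

Run the packaged 37-record pathogenic reference cohort through the
pipeline:

```r
t4 <- load_fixture("T4")
summarize_cohort(t4)
#> <cohort_summary> 37 records
#>   pathogenic/likely pathogenic          37/37 (100%)
#>   personal history of PGL/PCC           16/37 (43%)
#>   family history of PGL/PCC/GIST         5/37 (14%)
#>   same-gene somatic inactivating allele  13/37 (35%)
#>     second-hit split                    11 copy-loss / 2 SNV
#>   no somatic alteration                 23/37 (62%)
#>   IHC-concordant among second hits       8/37 (22%)
#>   per gene: SDHA=10  SDHB=13  SDHC=13  SDHD=1
```

16 of 37 carriers have a personal history of PGL/PCC; 13 tumors carry a
same-gene somatic second hit (11 one-copy deletions, 2 inactivating SNVs),
of which 8 show the gene-concordant IHC loss pattern; 23 tumors carry no
somatic SDHx alteration at all (one copy-number gain counts in neither
class). Batch-classify and build submission payloads:

```r
kb <- classify_batch(t4, rb)$knowledgebase
table(kb$category)
#>      NEGATIVE       NEUTRAL NOT_ACCOUNTED      POSITIVE
#>             2             1            28             6
payloads <- lapply(seq_len(nrow(kb)), function(i) build_submission(kb[i, ]))
log <- submit_batch(payloads)          # dry-run transport by default
table(log$status)                      # 37 x DRY_RUN
```

A command-line front end is installed under `exec/`:

```sh
hppgl classify --gene SDHA --personal NO --family NO --multifocal NO \
      --metastasis NO --somatic NO --kit-pdgfra WT \
      --ihc-sdha INTACT --ihc-sdhb INTACT     # -> A-V / NEGATIVE
hppgl batch --in cohort.tsv --out knowledgebase.tsv
hppgl validate-rules --mode strict
hppgl simulate --n 500 --seed 7 --out synthetic.tsv
```

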