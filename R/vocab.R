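# Controlled vocabularies shared across the package. Every field consulted by
# the rule matcher takes values from one of these sets; NA here is the literal
# string "NA" (not ascertained), never the R missing value.

SDH_GENES <- c("SDHA", "SDHB", "SDHC", "SDHD")

# SDHx plus the additional HPPGL-associated genes whose presence as a second
# germline variant disqualifies a record from framework matching.
HPPGL_GENES <- c(SDH_GENES, "SDHAF2", "MAX", "TMEM127", "EPAS1", "VHL",
                 "RET", "NF1")

TRISTATE <- c("YES", "NO", "NA")
IHC_LEVELS <- c("LOSS", "INTACT", "EQUIVOCAL", "NOT_TESTED")
KIT_PDGFRA_LEVELS <- c("WT", "NOT_WT", "NA")
GENE_STATUS_LEVELS <- c("WT", "MUTATED", "NOT_TESTED")
PARENT_ORIGIN_LEVELS <- c("PATERNAL", "MATERNAL", "NOT_TESTED")
COHORT_LEVELS <- c("GERMLINE_AND_TUMOR", "GERMLINE_ONLY", "TUMOR_ONLY")
GERMLINE_CLASSES <- c("PATHOGENIC", "LIKELY_PATHOGENIC", "VUS",
                      "LIKELY_BENIGN", "BENIGN", "NOT_REPORTED")
VARIANT_KINDS <- c("SNV", "INDEL", "COPY_LOSS", "COPY_GAIN", "STRUCTURAL",
                   "EXON_DELETION", "DUPLICATION", "NONE", "UNKNOWN")
CONSEQUENCE_CLASSES <- c("NONSENSE", "FRAMESHIFT", "CANONICAL_SPLICE",
                         "MISSENSE", "SYNONYMOUS", "INTRONIC_OTHER",
                         "INFRAME_INDEL", "COPY_LOSS", "COPY_GAIN",
                         "STRUCTURAL_DISRUPTIVE", "UNKNOWN")
CATEGORY_LEVELS <- c("POSITIVE", "NEUTRAL", "NEGATIVE", "NOT_ACCOUNTED")
NO_MATCH <- "NO_MATCH"

# The ten non-gene evidence columns of the framework, in table order.
EVIDENCE_COLUMNS <- c("additional_hppgl_germline", "personal_history",
                      "paternal_inheritance", "family_history", "multifocal",
                      "metastasis", "somatic_inactivating", "kit_pdgfra",
                      "ihc_sdha", "ihc_sdhb")

#' Genes recognised by the evidence framework
#'
#' `sdh_genes()` returns the four succinate dehydrogenase subunit genes the
#' framework assesses; `hppgl_genes()` returns the wider list of
#' HPPGL-associated genes in which an additional germline variant disqualifies
#' a record from framework matching.
#'
#' @return Character vector of gene symbols.
#' @export
#' @examples
#' sdh_genes()
sdh_genes <- function() SDH_GENES

#' @rdname sdh_genes
#' @export
hppgl_genes <- function() HPPGL_GENES

#' Value domains for the framework evidence columns
#'
#' Returns the legal value set for each of the ten non-gene evidence columns
#' consulted by the rule matcher. The product of these domains is the finite
#' evidence space enumerated by [check_exclusivity()].
#'
#' @return Named list of character vectors, one per evidence column.
#' @export
evidence_domains <- function() {
  list(
    additional_hppgl_germline = TRISTATE,
    personal_history          = TRISTATE,
    paternal_inheritance      = TRISTATE,
    family_history            = TRISTATE,
    multifocal                = TRISTATE,
    metastasis                = TRISTATE,
    somatic_inactivating      = TRISTATE,
    kit_pdgfra                = KIT_PDGFRA_LEVELS,
    ihc_sdha                  = IHC_LEVELS,
    ihc_sdhb                  = IHC_LEVELS
  )
}

# internal: scalar membership check that treats NULL/NA_character_ as illegal
is_enum <- function(x, levels) {
  is.character(x) && length(x) == 1L && !is.na(x) && x %in% levels
}
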