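# Record types housing every framework parameter and patient observation:
# germline variants, somatic alterations, clinical-genetics history,
# KIT/PDGFRA driver status, IHC results, and the per-variant evidence vector
# consulted by the rule matcher.

#' Construct a germline variant
#'
#' @param text Variant string, e.g. `"SDHB:c.137G>A (p.Arg46Gln)"`.
#' @param classification Reported germline classification; one of
#'   `"PATHOGENIC"`, `"LIKELY_PATHOGENIC"`, `"VUS"`, `"LIKELY_BENIGN"`,
#'   `"BENIGN"`, `"NOT_REPORTED"`.
#' @return Object of class `germline_variant`: list with `gene`, `hgvs_c`,
#'   `hgvs_p`, `kind`, `classification`, plus the raw `text`.
#' @export
germline_variant <- function(text, classification = "NOT_REPORTED") {
  pv <- parse_variant_string(text)
  structure(list(gene = pv$gene, hgvs_c = pv$cdna, hgvs_p = pv$protein,
                 kind = pv$kind, classification = classification,
                 text = text, parse_ok = pv$ok),
            class = "germline_variant")
}

#' Construct a clinical-genetics history
#'
#' Personal history is positive when the subject has a paraganglioma or
#' pheochromocytoma, with or without an associated GIST. An isolated GIST is
#' recorded via `personal_with_gist = TRUE` with
#' `personal_pgl_pcc = "NO"` and does not count as positive personal history.
#'
#' @param personal_pgl_pcc,family_pgl_pcc_gist,multifocal_extra_adrenal,metastasis
#'   Tri-state values: `"YES"`, `"NO"`, or `"NA"` (not ascertained).
#' @param personal_with_gist Logical; subject has a GIST.
#' @param parent_of_origin `"PATERNAL"`, `"MATERNAL"`, or `"NOT_TESTED"`.
#' @return Object of class `clinical_history`.
#' @export
clinical_history <- function(personal_pgl_pcc = "NA",
                             personal_with_gist = FALSE,
                             parent_of_origin = "NOT_TESTED",
                             family_pgl_pcc_gist = "NA",
                             multifocal_extra_adrenal = "NA",
                             metastasis = "NA") {
  structure(list(personal_pgl_pcc = personal_pgl_pcc,
                 personal_with_gist = personal_with_gist,
                 parent_of_origin = parent_of_origin,
                 family_pgl_pcc_gist = family_pgl_pcc_gist,
                 multifocal_extra_adrenal = multifocal_extra_adrenal,
                 metastasis = metastasis),
            class = "clinical_history")
}

#' Construct a KIT/PDGFRA driver-gene status
#'
#' Sporadic GISTs are usually driven by activating KIT or PDGFRA mutations;
#' SDH-deficient GISTs are wild-type for both. The combined status used by
#' the framework is `"WT"` only when both genes are wild-type.
#'
#' @param kit,pdgfra One of `"WT"`, `"MUTATED"`, `"NOT_TESTED"`.
#' @return Object of class `driver_gene_status`.
#' @export
driver_gene_status <- function(kit = "NOT_TESTED", pdgfra = "NOT_TESTED") {
  structure(list(kit = kit, pdgfra = pdgfra), class = "driver_gene_status")
}

# internal: combined KIT/PDGFRA framework value
combined_driver_status <- function(ds) {
  if (identical(ds$kit, "MUTATED") || identical(ds$pdgfra, "MUTATED")) return("NOT_WT")
  if (identical(ds$kit, "WT") && identical(ds$pdgfra, "WT")) return("WT")
  "NA"
}

#' Construct a patient record
#'
#' The merged germline/tumor/clinical/IHC observation for one subject, the
#' unit read from and written to cohort tables.
#'
#' @param subject_id Opaque subject identifier (never emitted in submissions).
#' @param cohort `"GERMLINE_AND_TUMOR"`, `"GERMLINE_ONLY"`, or
#'   `"TUMOR_ONLY"`.
#' @param germline_variants List of [germline_variant()] objects (the SDHx
#'   alleles under assessment).
#' @param other_germline List of [germline_variant()] objects reported in
#'   addition to the assessed allele (any gene).
#' @param other_germline_assessed Logical; `FALSE` when additional-germline
#'   status was not ascertained (absence is never coerced to a negative).
#' @param somatic_alterations List of [somatic_alteration()] objects.
#' @param somatic_assessed Logical; `FALSE` when no tumor sequencing was done.
#' @param clinical A [clinical_history()].
#' @param driver_status A [driver_gene_status()].
#' @param ihc_sdha,ihc_sdhb `"LOSS"`, `"INTACT"`, `"EQUIVOCAL"`, or
#'   `"NOT_TESTED"`.
#' @param diagnoses Character vector of free-text cancer labels (treated as
#'   PHI; excluded from submission payloads).
#' @return Object of class `patient_record`.
#' @export
patient_record <- function(subject_id,
                           cohort = "GERMLINE_AND_TUMOR",
                           germline_variants = list(),
                           other_germline = list(),
                           other_germline_assessed = TRUE,
                           somatic_alterations = list(),
                           somatic_assessed = TRUE,
                           clinical = clinical_history(),
                           driver_status = driver_gene_status(),
                           ihc_sdha = "NOT_TESTED",
                           ihc_sdhb = "NOT_TESTED",
                           diagnoses = character()) {
  structure(list(subject_id = subject_id, cohort = cohort,
                 germline_variants = germline_variants,
                 other_germline = other_germline,
                 other_germline_assessed = other_germline_assessed,
                 somatic_alterations = somatic_alterations,
                 somatic_assessed = somatic_assessed,
                 clinical = clinical, driver_status = driver_status,
                 ihc_sdha = ihc_sdha, ihc_sdhb = ihc_sdhb,
                 diagnoses = diagnoses),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  gl <- vapply(x$germline_variants, function(v) v$text, character(1))
  cat("<patient_record>", x$subject_id, sprintf("[%s]\n", x$cohort))
  cat("  germline:", if (length(gl)) paste(gl, collapse = "; ") else "(none)", "\n")
  cat("  somatic: ",
      if (length(x$somatic_alterations))
        paste(vapply(x$somatic_alterations,
                     function(a) if (a$kind == "NONE") "none" else
                       paste0(a$gene, " ", a$kind), character(1)),
              collapse = "; ")
      else if (isTRUE(x$somatic_assessed)) "negative" else "not assessed", "\n")
  cat("  IHC: SDHA", x$ihc_sdha, "/ SDHB", x$ihc_sdhb, "\n")
  invisible(x)
}

#' Validate a patient record
#'
#' Checks every type invariant: legal enumeration values throughout, parseable
#' variant strings, cohort consistency (germline-only records carry no somatic
#' alterations; tumor-only records carry no clinical-genetics evaluation), and
#' the personal-history/GIST constraint. Violations are returned as data, one
#' row per broken rule; the function is total and never raises on arbitrary
#' input.
#'
#' @param record A [patient_record()] (or anything; non-records are reported
#'   as a single violation).
#' @return A data frame with columns `field` and `message`; zero rows iff the
#'   record is valid.
#' @export
validate_record <- function(record) {
  v <- list()
  add <- function(field, message) v[[length(v) + 1L]] <<- list(field = field, message = message)

  if (!inherits(record, "patient_record") || !is.list(record)) {
    add("record", "not a patient_record object")
    return(violations_df(v))
  }
  if (!is.character(record$subject_id) || length(record$subject_id) != 1L ||
      is.na(record$subject_id) || !nzchar(record$subject_id)) {
    add("subject_id", "subject_id must be a non-empty string")
  }
  if (!is_enum(record$cohort, COHORT_LEVELS)) {
    add("cohort", paste("cohort must be one of:", paste(COHORT_LEVELS, collapse = ", ")))
  }

  for (i in seq_along(record$germline_variants)) {
    g <- record$germline_variants[[i]]
    lab <- paste0("germline_variants[", i, "]")
    if (!inherits(g, "germline_variant")) { add(lab, "not a germline_variant"); next }
    if (!isTRUE(g$parse_ok)) add(lab, paste0("variant string does not parse: '", g$text, "'"))
    if (is.na(g$gene) || !nzchar(g$gene)) add(lab, "gene symbol missing")
    if (is.na(g$hgvs_c) &&
        !g$kind %in% c("COPY_LOSS", "COPY_GAIN", "EXON_DELETION", "DUPLICATION", "STRUCTURAL")) {
      add(lab, "needs an HGVS c. description or a copy-number description")
    }
    if (!is_enum(g$classification, GERMLINE_CLASSES)) {
      add(lab, "illegal reported classification")
    }
  }
  for (i in seq_along(record$other_germline)) {
    g <- record$other_germline[[i]]
    lab <- paste0("other_germline[", i, "]")
    if (!inherits(g, "germline_variant")) { add(lab, "not a germline_variant"); next }
    if (!isTRUE(g$parse_ok)) add(lab, paste0("variant string does not parse: '", g$text, "'"))
  }
  for (i in seq_along(record$somatic_alterations)) {
    a <- record$somatic_alterations[[i]]
    lab <- paste0("somatic_alterations[", i, "]")
    if (!inherits(a, "somatic_alteration")) { add(lab, "not a somatic_alteration"); next }
    if (!is_enum(a$kind, VARIANT_KINDS)) add(lab, "illegal alteration kind")
    if (identical(a$kind, "NONE") && isTRUE(a$inactivating)) {
      add(lab, "kind NONE cannot be inactivating")
    }
    if (identical(a$kind, "COPY_GAIN") && isTRUE(a$inactivating)) {
      add(lab, "copy-number gain cannot be inactivating")
    }
  }

  cl <- record$clinical
  if (!inherits(cl, "clinical_history")) {
    add("clinical", "not a clinical_history")
  } else {
    for (f in c("personal_pgl_pcc", "family_pgl_pcc_gist",
                "multifocal_extra_adrenal", "metastasis")) {
      if (!is_enum(cl[[f]], TRISTATE)) add(f, "must be YES, NO or NA")
    }
    if (!is_enum(cl$parent_of_origin, PARENT_ORIGIN_LEVELS)) {
      add("parent_of_origin", "must be PATERNAL, MATERNAL or NOT_TESTED")
    }
    if (!is.logical(cl$personal_with_gist) || length(cl$personal_with_gist) != 1L ||
        is.na(cl$personal_with_gist)) {
      add("personal_with_gist", "must be TRUE or FALSE")
    } else if (isTRUE(cl$personal_with_gist) &&
               is_enum(cl$personal_pgl_pcc, TRISTATE) &&
               cl$personal_pgl_pcc == "NA") {
      add("personal_with_gist", "GIST flag requires ascertained personal history (YES or NO)")
    }
  }

  ds <- record$driver_status
  if (!inherits(ds, "driver_gene_status")) {
    add("driver_status", "not a driver_gene_status")
  } else {
    if (!is_enum(ds$kit, GENE_STATUS_LEVELS)) add("kit", "illegal KIT status")
    if (!is_enum(ds$pdgfra, GENE_STATUS_LEVELS)) add("pdgfra", "illegal PDGFRA status")
  }

  if (!is_enum(record$ihc_sdha, IHC_LEVELS)) add("ihc_sdha", "illegal IHC stain value")
  if (!is_enum(record$ihc_sdhb, IHC_LEVELS)) add("ihc_sdhb", "illegal IHC stain value")

  # cohort-consistency invariants
  if (is_enum(record$cohort, COHORT_LEVELS)) {
    real_somatic <- any(vapply(record$somatic_alterations,
                               function(a) inherits(a, "somatic_alteration") &&
                                 !identical(a$kind, "NONE"), logical(1)))
    if (record$cohort == "GERMLINE_ONLY" && real_somatic) {
      add("cohort", "GERMLINE_ONLY record carries somatic alterations")
    }
    if (record$cohort == "TUMOR_ONLY" && inherits(cl, "clinical_history")) {
      assessed <- any(vapply(c("personal_pgl_pcc", "family_pgl_pcc_gist",
                               "multifocal_extra_adrenal", "metastasis"),
                             function(f) is_enum(cl[[f]], TRISTATE) && cl[[f]] != "NA",
                             logical(1)))
      if (assessed) add("cohort", "TUMOR_ONLY record carries a clinical-genetics evaluation")
    }
    if (record$cohort == "TUMOR_ONLY" && length(record$germline_variants) > 0L) {
      add("cohort", "TUMOR_ONLY record carries germline variants")
    }
  }

  violations_df(v)
}

violations_df <- function(v) {
  if (length(v) == 0L) {
    return(data.frame(field = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(field = vapply(v, `[[`, character(1), "field"),
             message = vapply(v, `[[`, character(1), "message"),
             stringsAsFactors = FALSE)
}

#' Construct a framework evidence vector
#'
#' Houses the eleven evidence columns consulted by the rule matcher: the SDHx
#' gene plus the ten tri-state/enumerated parameters. This is the only object
#' the matcher reads.
#'
#' @param gene One of `"SDHA"`, `"SDHB"`, `"SDHC"`, `"SDHD"`.
#' @param additional_hppgl_germline,personal_history,paternal_inheritance,family_history,multifocal,metastasis,somatic_inactivating
#'   `"YES"`, `"NO"`, or `"NA"`.
#' @param kit_pdgfra `"WT"`, `"NOT_WT"`, or `"NA"`.
#' @param ihc_sdha,ihc_sdhb `"LOSS"`, `"INTACT"`, `"EQUIVOCAL"`,
#'   `"NOT_TESTED"`.
#' @return Object of class `evidence_vector`.
#' @export
#' @examples
#' evidence_vector("SDHA", personal_history = "YES")
evidence_vector <- function(gene,
                            additional_hppgl_germline = "NA",
                            personal_history = "NA",
                            paternal_inheritance = "NA",
                            family_history = "NA",
                            multifocal = "NA",
                            metastasis = "NA",
                            somatic_inactivating = "NA",
                            kit_pdgfra = "NA",
                            ihc_sdha = "NOT_TESTED",
                            ihc_sdhb = "NOT_TESTED") {
  ev <- structure(list(gene = gene,
                       additional_hppgl_germline = additional_hppgl_germline,
                       personal_history = personal_history,
                       paternal_inheritance = paternal_inheritance,
                       family_history = family_history,
                       multifocal = multifocal,
                       metastasis = metastasis,
                       somatic_inactivating = somatic_inactivating,
                       kit_pdgfra = kit_pdgfra,
                       ihc_sdha = ihc_sdha,
                       ihc_sdhb = ihc_sdhb),
                  class = "evidence_vector")
  probs <- validate_evidence(ev)
  if (length(probs)) stop("invalid evidence vector: ", paste(probs, collapse = "; "))
  ev
}

# internal: character vector of problems, empty if legal
validate_evidence <- function(ev) {
  probs <- character()
  if (!is_enum(ev$gene, SDH_GENES)) probs <- c(probs, "gene must be an SDHx gene")
  dom <- evidence_domains()
  for (col in EVIDENCE_COLUMNS) {
    if (!is_enum(ev[[col]], dom[[col]])) {
      probs <- c(probs, paste0(col, " must be one of: ", paste(dom[[col]], collapse = ", ")))
    }
  }
  probs
}

#' @export
print.evidence_vector <- function(x, ...) {
  cat("<evidence_vector>", x$gene, "\n")
  for (col in EVIDENCE_COLUMNS) cat(sprintf("  %-26s %s\n", col, x[[col]]))
  invisible(x)
}
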