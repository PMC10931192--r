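# Batch processing: reading and writing cohort tables, merging germline /
# tumor / clinical sources into an integrated database, deriving the
# per-variant evidence vector, classifying in batch, and cohort summaries.

COHORT_TABLE_COLUMNS <- c("subject_id", "cohort", "germline_variants",
                          "germline_classification", "other_germline",
                          "personal_history", "parent_of_origin",
                          "family_history", "multifocal", "metastasis",
                          "somatic_alterations", "kit_status", "pdgfra_status",
                          "ihc_sdha", "ihc_sdhb", "diagnoses")

# -- field-level token parsers (the dialect of clinical report tables) -------

parse_tristate_token <- function(x) {
  x <- trimws(x)
  if (!nzchar(x) || toupper(x) %in% c("NA", "N/A", "NT")) return("NA")
  if (grepl("^yes", x, ignore.case = TRUE)) return("YES")
  if (grepl("^(no|neg)", x, ignore.case = TRUE)) return("NO")
  "NA"
}

parse_personal_token <- function(x) {
  x <- trimws(x)
  gist <- grepl("gist", x, ignore.case = TRUE)
  list(personal = parse_tristate_token(sub("\\(.*\\)", "", x)), gist = gist)
}

parse_parent_token <- function(x) {
  x <- tolower(trimws(x))
  if (grepl("patern", x)) return("PATERNAL")
  if (grepl("matern", x)) return("MATERNAL")
  "NOT_TESTED"
}

parse_ihc_token <- function(x) {
  x <- tolower(trimws(x))
  if (!nzchar(x) || x %in% c("nt", "na", "n/a", "not tested")) return("NOT_TESTED")
  if (grepl("loss|lost|deficien", x)) return("LOSS")
  if (grepl("intact|normal|retain", x)) return("INTACT")
  if (grepl("equivocal", x)) return("EQUIVOCAL")
  x  # illegal literal surfaces as a validation violation downstream
}

parse_gene_status_token <- function(x) {
  x <- trimws(x)
  if (toupper(x) == "WT") return("WT")
  if (!nzchar(x) || toupper(x) %in% c("NT", "NA", "N/A")) return("NOT_TESTED")
  "MUTATED"  # any reported variant string
}

parse_classification_token <- function(x) {
  switch(toupper(trimws(x)),
         "P" = , "PATHOGENIC" = "PATHOGENIC",
         "LP" = , "LIKELY PATHOGENIC" = , "LIKELY_PATHOGENIC" = "LIKELY_PATHOGENIC",
         "VUS" = "VUS",
         "LB" = , "LIKELY BENIGN" = , "LIKELY_BENIGN" = "LIKELY_BENIGN",
         "B" = , "BENIGN" = "BENIGN",
         "NOT_REPORTED")
}

split_variant_list <- function(x) {
  x <- trimws(x)
  if (!nzchar(x) || toupper(x) %in% c("NEG", "NEGATIVE", "NO", "NA", "N/A", "NONE")) {
    return(character())
  }
  x <- sub("^Yes,\\s*", "", x)
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

# -- reading --------------------------------------------------------------

#' Read a cohort table into patient records
#'
#' Reads a tab-delimited cohort table (one row per subject, documented header;
#' see the package vignette for the column dialect) into a list of
#' [patient_record()] objects. Unknown columns produce a warning and are
#' ignored; missing columns yield not-ascertained (`"NA"`) fields — absence is
#' never coerced to a negative. Every row is passed through
#' [validate_record()]; violations are attached to each record as attribute
#' `"violations"`.
#'
#' @param path Path to a tab-delimited text file with a header row.
#' @return List of `patient_record` objects.
#' @seealso [write_cohort_table()], [load_fixture()]
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("cohort table not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = NULL,
                           quote = "", check.names = FALSE)
  unknown <- setdiff(names(tab), COHORT_TABLE_COLUMNS)
  if (length(unknown)) {
    warning("ignoring unknown column(s): ", paste(unknown, collapse = ", "))
  }
  if (!"subject_id" %in% names(tab)) {
    stop("cohort table header must include 'subject_id'")
  }
  for (col in setdiff(COHORT_TABLE_COLUMNS, names(tab))) {
    tab[[col]] <- rep("", nrow(tab))
  }

  records <- lapply(seq_len(nrow(tab)), function(i) row_to_record(tab[i, ]))
  ids <- vapply(records, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids)) {
    warning("duplicate subject_id value(s): ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  records
}

row_to_record <- function(row) {
  cls <- parse_classification_token(row$germline_classification)
  germ <- lapply(split_variant_list(row$germline_variants),
                 germline_variant, classification = cls)
  other_raw <- trimws(row$other_germline)
  other_assessed <- nzchar(other_raw) && !toupper(other_raw) %in% c("NA", "N/A")
  other <- lapply(split_variant_list(row$other_germline), germline_variant)

  som_raw <- trimws(row$somatic_alterations)
  som_assessed <- nzchar(som_raw) && !toupper(som_raw) %in% c("NA", "N/A")
  som <- lapply(split_variant_list(row$somatic_alterations), somatic_alteration)

  pers <- parse_personal_token(row$personal_history)
  cohort <- toupper(trimws(row$cohort))
  if (!cohort %in% COHORT_LEVELS) cohort <- "GERMLINE_AND_TUMOR"
  diagnoses <- trimws(strsplit(row$diagnoses, ";", fixed = TRUE)[[1]])
  diagnoses <- diagnoses[nzchar(diagnoses)]

  rec <- patient_record(
    subject_id = trimws(row$subject_id),
    cohort = cohort,
    germline_variants = germ,
    other_germline = other,
    other_germline_assessed = other_assessed,
    somatic_alterations = som,
    somatic_assessed = som_assessed,
    clinical = clinical_history(
      personal_pgl_pcc = pers$personal,
      personal_with_gist = pers$gist,
      parent_of_origin = parse_parent_token(row$parent_of_origin),
      family_pgl_pcc_gist = parse_tristate_token(row$family_history),
      multifocal_extra_adrenal = parse_tristate_token(row$multifocal),
      metastasis = parse_tristate_token(row$metastasis)),
    driver_status = driver_gene_status(
      kit = parse_gene_status_token(row$kit_status),
      pdgfra = parse_gene_status_token(row$pdgfra_status)),
    ihc_sdha = parse_ihc_token(row$ihc_sdha),
    ihc_sdhb = parse_ihc_token(row$ihc_sdhb),
    diagnoses = diagnoses)
  attr(rec, "violations") <- validate_record(rec)
  rec
}

# -- writing --------------------------------------------------------------

format_tristate_token <- function(x, yes = "Yes", no = "Neg") {
  switch(x, YES = yes, NO = no, "NA")
}

record_to_row <- function(rec) {
  cl <- rec$clinical
  pers <- format_tristate_token(cl$personal_pgl_pcc, no = "No")
  if (isTRUE(cl$personal_with_gist)) {
    pers <- if (cl$personal_pgl_pcc == "YES") "Yes (+GIST)" else "No (GIST)"
  }
  germ_cls <- if (length(rec$germline_variants))
    rec$germline_variants[[1L]]$classification else "NOT_REPORTED"
  cls_token <- c(PATHOGENIC = "P", LIKELY_PATHOGENIC = "LP", VUS = "VUS",
                 LIKELY_BENIGN = "LB", BENIGN = "B", NOT_REPORTED = "")[germ_cls]
  som <- vapply(rec$somatic_alterations, function(a)
    format_variant(structure(list(gene = a$gene, cdna = a$hgvs_c,
                                  protein = a$hgvs_p, kind = a$kind, ok = TRUE),
                             class = "parsed_variant")), character(1))
  data.frame(
    subject_id = rec$subject_id,
    cohort = rec$cohort,
    germline_variants = paste(vapply(rec$germline_variants, `[[`,
                                     character(1), "text"), collapse = "; "),
    germline_classification = unname(cls_token),
    other_germline = if (!isTRUE(rec$other_germline_assessed)) "NA"
      else if (length(rec$other_germline) == 0L) "Neg"
      else paste(vapply(rec$other_germline, `[[`, character(1), "text"),
                 collapse = "; "),
    personal_history = pers,
    parent_of_origin = c(PATERNAL = "Paternal", MATERNAL = "Maternal",
                         NOT_TESTED = "NT")[cl$parent_of_origin],
    family_history = format_tristate_token(cl$family_pgl_pcc_gist),
    multifocal = format_tristate_token(cl$multifocal_extra_adrenal),
    metastasis = format_tristate_token(cl$metastasis),
    somatic_alterations = if (!isTRUE(rec$somatic_assessed)) "NA"
      else if (length(som) == 0L) "Neg" else paste(som, collapse = "; "),
    kit_status = c(WT = "WT", MUTATED = "Mutated",
                   NOT_TESTED = "NT")[rec$driver_status$kit],
    pdgfra_status = c(WT = "WT", MUTATED = "Mutated",
                      NOT_TESTED = "NT")[rec$driver_status$pdgfra],
    ihc_sdha = c(LOSS = "Loss", INTACT = "Intact", EQUIVOCAL = "Equivocal",
                 NOT_TESTED = "NT")[rec$ihc_sdha],
    ihc_sdhb = c(LOSS = "Loss", INTACT = "Intact", EQUIVOCAL = "Equivocal",
                 NOT_TESTED = "NT")[rec$ihc_sdhb],
    diagnoses = paste(rec$diagnoses, collapse = "; "),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Write patient records to a cohort table
#'
#' Serializes records to the tab-delimited cohort format read by
#' [read_cohort_table()]; the two functions round-trip.
#'
#' @param records List of `patient_record` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(records, path) {
  rows <- do.call(rbind, lapply(records, record_to_row))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

# -- evidence derivation ---------------------------------------------------

# internal: indices of assessable germline SDHx variants
assessable_variants <- function(rec) {
  which(vapply(rec$germline_variants, function(g)
    inherits(g, "germline_variant") && !is.na(g$gene) && g$gene %in% SDH_GENES,
    logical(1)))
}

#' Derive the framework evidence vector for a record
#'
#' Maps a patient record onto the eleven framework columns for one assessable
#' germline SDHx variant. The somatic-inactivating column is `"YES"` only
#' when a same-gene somatic alteration is an inactivating allele (the second
#' hit is gene-scoped); the additional-germline column is `"YES"` when any
#' second qualifying germline variant exists (a second SDHx variant, or a
#' variant in another HPPGL-associated gene); KIT/PDGFRA status is `"WT"`
#' only when both genes are wild-type.
#'
#' @param record A valid `patient_record` with at least one germline SDHx
#'   variant.
#' @param variant Index of the assessed variant among the record's
#'   assessable SDHx variants (default the first).
#' @return An [evidence_vector()].
#' @export
derive_evidence <- function(record, variant = 1L) {
  idx <- assessable_variants(record)
  if (length(idx) == 0L) {
    stop("record ", record$subject_id,
         " has no assessable germline SDHx variant")
  }
  if (variant > length(idx)) stop("variant index out of range")
  g <- record$germline_variants[[idx[variant]]]
  gene <- g$gene

  n_qualifying_other <- sum(vapply(record$other_germline, function(o)
    inherits(o, "germline_variant") && !is.na(o$gene) && o$gene %in% HPPGL_GENES,
    logical(1)))
  additional <-
    if (length(idx) > 1L || n_qualifying_other > 0L) "YES"
    else if (isTRUE(record$other_germline_assessed)) "NO"
    else "NA"

  cl <- record$clinical
  paternal <- switch(cl$parent_of_origin,
                     PATERNAL = "YES", MATERNAL = "NO", "NA")

  tumor_assessed <- isTRUE(record$somatic_assessed) &&
    record$cohort != "GERMLINE_ONLY"
  somatic <- if (!tumor_assessed) "NA" else {
    hit <- any(vapply(record$somatic_alterations, function(a)
      identical(a$gene, gene) && isTRUE(a$inactivating), logical(1)))
    if (hit) "YES" else "NO"
  }

  evidence_vector(
    gene = gene,
    additional_hppgl_germline = additional,
    personal_history = cl$personal_pgl_pcc,
    paternal_inheritance = paternal,
    family_history = cl$family_pgl_pcc_gist,
    multifocal = cl$multifocal_extra_adrenal,
    metastasis = cl$metastasis,
    somatic_inactivating = somatic,
    kit_pdgfra = combined_driver_status(record$driver_status),
    ihc_sdha = record$ihc_sdha,
    ihc_sdhb = record$ihc_sdhb)
}

# -- batch classification --------------------------------------------------

#' Classify a batch of records into the knowledgebase
#'
#' Derives the evidence vector for every assessable germline SDHx variant of
#' every record and matches it against the rulebook, producing one
#' knowledgebase row per (subject, variant) with a per-record log line.
#' Records with no assessable variant, or whose evidence cannot be derived,
#' are logged and skipped; the run never aborts on a single record. Output is
#' deterministic given the inputs and matching mode, and independent of input
#' row order.
#'
#' @param records List of `patient_record` objects.
#' @param rb A [load_rulebook()] rulebook.
#' @return List with elements `knowledgebase` (data frame: subject, variant,
#'   the ten evidence columns prefixed `ev_`, matched code, category, comment,
#'   disqualifiers, QC flags, timestamp) and `log` (character vector, one
#'   header plus one line per processed variant).
#' @export
classify_batch <- function(records, rb) {
  stopifnot(inherits(rb, "rulebook"))
  log <- sprintf("# rulebook %s mode=%s records=%d",
                 rb$version, rb$mode, length(records))
  rows <- list()
  stamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")

  for (rec in records) {
    viol <- attr(rec, "violations")
    if (is.null(viol)) viol <- validate_record(rec)
    qc <- paste(unique(viol$field), collapse = ",")
    idx <- assessable_variants(rec)
    if (length(idx) == 0L) {
      log <- c(log, sprintf("%s\tNA\tSKIPPED\tno assessable germline SDHx variant",
                            rec$subject_id))
      next
    }
    for (k in seq_along(idx)) {
      res <- tryCatch(match_rule(rb, derive_evidence(rec, k)),
                      error = function(e) e)
      g <- rec$germline_variants[[idx[k]]]
      if (inherits(res, "error")) {
        log <- c(log, sprintf("%s\t%s\tFAILED\t%s", rec$subject_id, g$gene,
                              conditionMessage(res)))
        next
      }
      flags <- qc
      if (length(idx) > 1L) {
        flags <- paste(c(flags[nzchar(flags)], "MULTIPLE_GERMLINE"), collapse = ",")
      }
      ev <- res$evidence
      evcols <- as.list(unlist(ev[EVIDENCE_COLUMNS]))
      names(evcols) <- paste0("ev_", EVIDENCE_COLUMNS)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = rec$subject_id, gene = g$gene,
        hgvs_c = g$hgvs_c, hgvs_p = g$hgvs_p, variant_text = g$text,
        reported_classification = g$classification,
        as.data.frame(evcols, stringsAsFactors = FALSE),
        code = res$matched_code, category = res$category,
        comment = res$comment,
        disqualifiers = paste(res$disqualifiers, collapse = ","),
        qc_flags = flags, timestamp = stamp,
        row.names = NULL, stringsAsFactors = FALSE)
      log <- c(log, sprintf("%s\t%s\t%s\t%s%s", rec$subject_id, g$gene,
                            res$matched_code, res$category,
                            if (nzchar(flags)) paste0("\t", flags) else ""))
    }
  }
  kb <- if (length(rows)) do.call(rbind, rows) else NULL
  list(knowledgebase = kb, log = log)
}

#' Re-classify knowledgebase rows from their evidence snapshots
#'
#' Rebuilds the evidence vector stored in each knowledgebase row (the `ev_`
#' columns) and matches it again; used to confirm that classification is a
#' pure function of the evidence snapshot.
#'
#' @param kb A `classify_batch()$knowledgebase` data frame.
#' @param rb A rulebook.
#' @return Character vector of matched codes, one per row.
#' @export
reclassify_snapshots <- function(kb, rb) {
  vapply(seq_len(nrow(kb)), function(i) {
    args <- as.list(kb[i, paste0("ev_", EVIDENCE_COLUMNS)])
    names(args) <- EVIDENCE_COLUMNS
    ev <- do.call(evidence_vector, c(list(gene = kb$gene[i]), args))
    match_rule(rb, ev)$matched_code
  }, character(1))
}

# -- summaries -------------------------------------------------------------

# internal: the same-gene inactivating somatic alterations of a record
second_hits <- function(rec) {
  idx <- assessable_variants(rec)
  if (length(idx) == 0L) return(list())
  gene <- rec$germline_variants[[idx[1L]]]$gene
  Filter(function(a) identical(a$gene, gene) && isTRUE(a$inactivating),
         rec$somatic_alterations)
}

# internal: gene-concordant IHC pattern given a germline gene.
# SDHA inactivation ablates both stains; inactivation of the other subunits
# ablates SDHB staining while SDHA remains interpretable. Equivocal or
# not-performed stains on the required side are non-concordant.
ihc_concordant <- function(gene, ihc_sdha, ihc_sdhb) {
  if (gene == "SDHA") {
    ihc_sdha == "LOSS" && ihc_sdhb == "LOSS"
  } else {
    ihc_sdhb == "LOSS" && ihc_sdha != "LOSS"
  }
}

#' Summarize a cohort of patient records
#'
#' Computes the cohort-level counts the framework reports: records with a
#' pathogenic/likely-pathogenic assessed variant, positive personal and
#' family history, same-gene somatic inactivating alleles (split into
#' copy-loss and inactivating SNV/indel second hits), records with no somatic
#' alteration at all (copy-number gains fall in neither class), and — among
#' second-hit cases — those with a gene-concordant IHC loss pattern.
#' Percentages are reported as `round(100 * k / n)` alongside the raw
#' fractions.
#'
#' @param records List of `patient_record` objects from one cohort table.
#' @return Object of class `cohort_summary`: a list of counts, a `per_gene`
#'   table, and a `percent` vector.
#' @export
summarize_cohort <- function(records) {
  n <- length(records)
  genes <- vapply(records, function(r) {
    idx <- assessable_variants(r)
    if (length(idx)) r$germline_variants[[idx[1L]]]$gene else NA_character_
  }, character(1))

  is_plp <- vapply(records, function(r) {
    idx <- assessable_variants(r)
    length(idx) > 0L && r$germline_variants[[idx[1L]]]$classification %in%
      c("PATHOGENIC", "LIKELY_PATHOGENIC")
  }, logical(1))
  personal <- vapply(records, function(r)
    r$clinical$personal_pgl_pcc == "YES", logical(1))
  family <- vapply(records, function(r)
    r$clinical$family_pgl_pcc_gist == "YES", logical(1))

  hits <- lapply(records, second_hits)
  has_hit <- vapply(hits, function(h) length(h) > 0L, logical(1))
  copy_hit <- vapply(hits, function(h)
    length(h) > 0L && any(vapply(h, function(a)
      a$kind %in% c("COPY_LOSS", "EXON_DELETION", "STRUCTURAL"),
      logical(1))), logical(1))
  snv_hit <- has_hit & !copy_hit
  no_somatic <- vapply(records, function(r)
    isTRUE(r$somatic_assessed) && length(r$somatic_alterations) == 0L,
    logical(1))
  concordant <- vapply(seq_along(records), function(i) {
    has_hit[i] && ihc_concordant(genes[i], records[[i]]$ihc_sdha,
                                 records[[i]]$ihc_sdhb)
  }, logical(1))

  counts <- list(
    n_records = n,
    n_plp = sum(is_plp),
    n_personal_history = sum(personal),
    n_family_history = sum(family),
    n_somatic_inactivating = sum(has_hit),
    n_copy_loss_second_hit = sum(copy_hit),
    n_snv_second_hit = sum(snv_hit),
    n_no_somatic_alteration = sum(no_somatic),
    n_ihc_concordant_among_second_hit = sum(concordant))
  pct <- if (n > 0) {
    vapply(counts[-1L], function(k) round(100 * k / n), numeric(1))
  } else {
    vapply(counts[-1L], function(k) 0, numeric(1))
  }
  structure(c(counts,
              list(per_gene = table(factor(genes, levels = SDH_GENES)),
                   percent = pct)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>", x$n_records, "records\n")
  fmt <- function(k, label) {
    cat(sprintf("  %-36s %3d/%d (%d%%)\n", label, k, x$n_records,
                if (x$n_records > 0) round(100 * k / x$n_records) else 0))
  }
  fmt(x$n_plp, "pathogenic/likely pathogenic")
  fmt(x$n_personal_history, "personal history of PGL/PCC")
  fmt(x$n_family_history, "family history of PGL/PCC/GIST")
  fmt(x$n_somatic_inactivating, "same-gene somatic inactivating allele")
  cat(sprintf("    %-34s %3d copy-loss / %d SNV\n", "second-hit split",
              x$n_copy_loss_second_hit, x$n_snv_second_hit))
  fmt(x$n_no_somatic_alteration, "no somatic alteration")
  fmt(x$n_ihc_concordant_among_second_hit, "IHC-concordant among second hits")
  cat("  per gene:", paste(names(x$per_gene), as.integer(x$per_gene),
                           sep = "=", collapse = "  "), "\n")
  invisible(x)
}

# -- integrated somatic and germline merge ---------------------------------

#' Merge germline, tumor and clinical sources into an integrated database
#'
#' Joins per-subject source tables on `subject_id` and partitions subjects by
#' data availability: present in both germline and tumor sources (the fully
#' integrated cohort), germline-only, or tumor-only. Field-level conflicts
#' (the same column reported differently by two sources) are collected and
#' reported, never silently overwritten — the first source's value wins.
#'
#' @param germline,tumor Data frames keyed by `subject_id` carrying
#'   germline-side and tumor-side cohort-table columns.
#' @param clinical Optional data frame keyed by `subject_id` with
#'   clinical-history columns.
#' @return List with `table` (merged cohort-format data frame with a `cohort`
#'   column), `partition` (named counts), and `conflicts` (data frame:
#'   `subject_id`, `column`, `value_a`, `value_b`).
#' @export
merge_isgd <- function(germline, tumor, clinical = NULL) {
  check_source <- function(df, name) {
    if (!is.data.frame(df) || !"subject_id" %in% names(df)) {
      stop(name, " source must be a data frame with a subject_id column")
    }
    if (anyDuplicated(df$subject_id)) {
      stop("duplicate subject_id in ", name, " source: ",
           paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
    }
  }
  check_source(germline, "germline")
  check_source(tumor, "tumor")
  if (!is.null(clinical)) check_source(clinical, "clinical")

  ids <- union(germline$subject_id, tumor$subject_id)
  cohort <- ifelse(ids %in% germline$subject_id & ids %in% tumor$subject_id,
                   "GERMLINE_AND_TUMOR",
                   ifelse(ids %in% germline$subject_id, "GERMLINE_ONLY",
                          "TUMOR_ONLY"))
  out <- data.frame(subject_id = ids, cohort = cohort,
                    stringsAsFactors = FALSE)
  conflicts <- list()
  absorb <- function(out, src) {
    m <- match(out$subject_id, src$subject_id)
    for (col in setdiff(names(src), "subject_id")) {
      vals <- src[[col]][m]
      if (!col %in% names(out)) {
        out[[col]] <- ifelse(is.na(m), "", vals)
      } else {
        clash <- !is.na(m) & nzchar(out[[col]]) & nzchar(vals) &
          out[[col]] != vals
        if (any(clash)) {
          conflicts[[length(conflicts) + 1L]] <<- data.frame(
            subject_id = out$subject_id[clash], column = col,
            value_a = out[[col]][clash], value_b = vals[clash],
            stringsAsFactors = FALSE)
        }
        fill <- !is.na(m) & !nzchar(out[[col]]) & nzchar(vals)
        out[[col]][fill] <- vals[fill]
      }
    }
    out
  }
  out <- absorb(out, germline)
  out <- absorb(out, tumor)
  if (!is.null(clinical)) out <- absorb(out, clinical)

  for (col in setdiff(COHORT_TABLE_COLUMNS, names(out))) out[[col]] <- ""
  out <- out[COHORT_TABLE_COLUMNS]
  list(table = out,
       partition = c(GERMLINE_AND_TUMOR = sum(cohort == "GERMLINE_AND_TUMOR"),
                     GERMLINE_ONLY = sum(cohort == "GERMLINE_ONLY"),
                     TUMOR_ONLY = sum(cohort == "TUMOR_ONLY")),
       conflicts = if (length(conflicts)) do.call(rbind, conflicts) else
         data.frame(subject_id = character(), column = character(),
                    value_a = character(), value_b = character(),
                    stringsAsFactors = FALSE))
}
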