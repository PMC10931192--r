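# Parsing of the variant-string dialect used in clinical SDHx reports
# ("GENE:c.X (p.Y)", "GENE One Copy Deletion", "GENE EX1_9 Del", ...) and
# consequence classification, including the somatic "second hit"
# (inactivating allele) determination under the two-hit model.

#' Parse a clinical variant string
#'
#' Parses the free-text dialect used for germline and somatic SDHx variants:
#' HGVS-style `"GENE:c.X (p.Y)"` strings, copy-number phrases
#' (`"One Copy Deletion"`, `"Copy Number Gain"`, `"Gain (estimated 6 copies)"`),
#' exon-level deletions (`"EX1_9 Del"`), and whole-gene duplications.
#'
#' Parsing never raises on malformed input: an unparseable string yields a
#' descriptor with `ok = FALSE` and a message, so batch processing can log and
#' continue.
#'
#' @param text A single variant string, e.g. `"SDHC:c.397C>T (p.Arg133Ter)"`.
#' @return An object of class `parsed_variant`: a list with elements `gene`,
#'   `cdna`, `protein`, `kind` (one of SNV, INDEL, COPY_LOSS, COPY_GAIN,
#'   STRUCTURAL, EXON_DELETION, DUPLICATION, UNKNOWN), `ok`, and `message`.
#' @seealso [consequence_class()], [format_variant()]
#' @export
#' @examples
#' parse_variant_string("SDHC:c.397C>T (p.Arg133Ter)")
#' parse_variant_string("SDHB One Copy Deletion")
parse_variant_string <- function(text) {
  fail <- function(msg) {
    structure(list(gene = NA_character_, cdna = NA_character_,
                   protein = NA_character_, kind = "UNKNOWN",
                   ok = FALSE, message = msg),
              class = "parsed_variant")
  }
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    return(fail("variant string must be a single character value"))
  }
  txt <- gsub("\\*", "", trimws(text))
  if (!nzchar(txt)) return(fail("empty variant string"))

  # gene prefix: token before ":" or first whitespace
  m <- regexec("^([A-Za-z][A-Za-z0-9]*)\\s*[: ]\\s*(.*)$", txt)
  parts <- regmatches(txt, m)[[1]]
  if (length(parts) != 3L) return(fail(paste0("malformed gene prefix in '", txt, "'")))
  gene <- toupper(parts[2L])
  rest <- trimws(parts[3L])
  if (!nzchar(rest)) return(fail(paste0("no variant description after gene in '", txt, "'")))

  ok <- function(cdna, protein, kind) {
    structure(list(gene = gene, cdna = cdna, protein = protein, kind = kind,
                   ok = TRUE, message = ""),
              class = "parsed_variant")
  }

  # copy-number / structural phrases (case-insensitive)
  low <- tolower(rest)
  if (grepl("copy deletion", low)) return(ok(NA_character_, NA_character_, "COPY_LOSS"))
  if (grepl("copy number gain|^gain\\b|\\bgain\\b", low)) {
    return(ok(NA_character_, NA_character_, "COPY_GAIN"))
  }
  if (grepl("^ex[0-9_'a-z]*.*\\bdel\\b|^ex[0-9]", low) && grepl("del", low)) {
    return(ok(NA_character_, NA_character_, "EXON_DELETION"))
  }
  if (grepl("^duplication$", low)) return(ok(NA_character_, NA_character_, "DUPLICATION"))

  # HGVS-style: optional "c." prefix, optional "(p.___)" suffix
  m2 <- regexec("^(c\\.)?([^()]+?)\\s*(\\(\\s*(p\\.[^)]+)\\s*\\))?$", rest)
  p2 <- regmatches(rest, m2)[[1]]
  if (length(p2) == 0L) return(fail(paste0("unparseable variant description '", rest, "'")))
  cdna_body <- trimws(p2[3L])
  protein <- if (nzchar(p2[5L])) trimws(p2[5L]) else NA_character_
  if (!nzchar(cdna_body)) return(fail(paste0("empty coding description in '", txt, "'")))
  cdna <- paste0("c.", sub("^c\\.", "", cdna_body))

  kind <- variant_kind_from_hgvs(cdna, protein)
  ok(cdna, protein, kind)
}

# internal: small-variant kind from the HGVS c./p. text
variant_kind_from_hgvs <- function(cdna, protein) {
  # whole-gene/region duplications with uncertain breakpoints, e.g.
  # c.-30-?_2318+?dup, are structural duplications, not small indels
  if (grepl("\\?", cdna) && grepl("dup", cdna)) return("DUPLICATION")
  if (grepl("delins|del|dup|ins", cdna, ignore.case = TRUE)) return("INDEL")
  if (!is.na(protein) && grepl("delins|del|dup|fs", protein)) return("INDEL")
  if (grepl(">", cdna, fixed = TRUE)) return("SNV")
  "UNKNOWN"
}

#' Format a parsed variant back to its string form
#'
#' Inverse of [parse_variant_string()] up to whitespace normalisation; used to
#' check that parsing is stable under a parse-format-parse round trip.
#'
#' @param v A `parsed_variant`.
#' @return A single character string.
#' @export
format_variant <- function(v) {
  stopifnot(inherits(v, "parsed_variant"))
  if (!v$ok) return(NA_character_)
  if (v$kind == "COPY_LOSS") return(paste(v$gene, "One Copy Deletion"))
  if (v$kind == "COPY_GAIN") return(paste(v$gene, "Copy Number Gain"))
  if (v$kind == "EXON_DELETION") return(paste(v$gene, "Exon Del"))
  if (v$kind == "DUPLICATION" && is.na(v$cdna)) return(paste(v$gene, "Duplication"))
  out <- paste0(v$gene, ":", v$cdna)
  if (!is.na(v$protein)) out <- paste0(out, " (", v$protein, ")")
  out
}

#' @export
print.parsed_variant <- function(x, ...) {
  if (x$ok) {
    cat("<parsed_variant>", format_variant(x), sprintf("[%s]\n", x$kind))
  } else {
    cat("<parsed_variant> parse failure:", x$message, "\n")
  }
  invisible(x)
}

#' Classify the molecular consequence of a parsed variant
#'
#' Deterministic mapping from HGVS notation to a consequence class:
#' `p.*fs` suffixes are frameshifts, terminal `Ter`/`*` are nonsense,
#' intronic changes at offsets +/-1 or +/-2 disrupt the canonical splice
#' sites while deeper intronic offsets do not, single-residue substitutions
#' are missense, and copy-number/structural kinds pass through. The mapping
#' is a pure function of the notation (no transcript model is consulted).
#'
#' @param v A successfully parsed `parsed_variant`.
#' @return One of the consequence-class labels (see `CONSEQUENCE_CLASSES`
#'   internally), e.g. `"NONSENSE"`, `"CANONICAL_SPLICE"`, `"MISSENSE"`.
#' @export
#' @examples
#' consequence_class(parse_variant_string("SDHC:c.397C>T (p.Arg133Ter)"))
#' consequence_class(parse_variant_string("SDHA:c.1432+1G>C"))
consequence_class <- function(v) {
  stopifnot(inherits(v, "parsed_variant"))
  if (!v$ok) return("UNKNOWN")
  switch(v$kind,
    COPY_LOSS = return("COPY_LOSS"),
    COPY_GAIN = return("COPY_GAIN"),
    EXON_DELETION = return("STRUCTURAL_DISRUPTIVE"),
    STRUCTURAL = return("STRUCTURAL_DISRUPTIVE"),
    DUPLICATION = return("UNKNOWN"),
    NONE = return("UNKNOWN"),
    NULL
  )

  p <- v$protein
  if (!is.na(p) && nzchar(p)) {
    if (grepl("fs", p)) return("FRAMESHIFT")
    if (grepl("(Ter|\\*)[0-9]*$", p)) return("NONSENSE")
    if (grepl("=", p, fixed = TRUE)) return("SYNONYMOUS")
    if (grepl("^p\\.\\(?[A-Za-z]{1,3}[0-9]+(_[A-Za-z]{1,3}[0-9]+)?(del|dup)\\)?$", p)) {
      return("INFRAME_INDEL")
    }
    if (grepl("^p\\.\\(?[A-Za-z]{1,3}[0-9]+[A-Za-z]{1,3}\\)?$", p)) {
      return("MISSENSE")
    }
    return("UNKNOWN")
  }

  # cDNA-only descriptions: intronic offsets
  m <- regexec("^c\\.-?[0-9]+([+-][0-9]+)", v$cdna)
  parts <- regmatches(v$cdna, m)[[1]]
  if (length(parts) == 2L) {
    offset <- abs(as.integer(parts[2L]))
    if (!is.na(offset)) {
      return(if (offset <= 2L) "CANONICAL_SPLICE" else "INTRONIC_OTHER")
    }
  }
  if (v$kind == "INDEL") return("UNKNOWN")
  "UNKNOWN"
}

# Consequences that complete the two-hit model when observed somatically.
INACTIVATING_CONSEQUENCES <- c("NONSENSE", "FRAMESHIFT", "CANONICAL_SPLICE",
                               "COPY_LOSS", "STRUCTURAL_DISRUPTIVE")

#' Is a somatic alteration an inactivating allele (second hit)?
#'
#' SDHx genes are tumor suppressors inactivated through a two-hit model: a
#' germline variant is supported when the tumor carries a somatic
#' inactivating allele in the same gene. An alteration counts as inactivating
#' when its consequence is nonsense, frameshift, canonical +/-1,2 splice
#' disruption, one-copy loss, exon-level deletion, or a disruptive structural
#' variant. Missense, synonymous, deeper intronic changes and copy-number
#' gains never count; an absent alteration (`kind = "NONE"`) is not a hit.
#'
#' @param a A `somatic_alteration` (see [somatic_alteration()]) or a
#'   `parsed_variant`.
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' is_inactivating(somatic_alteration("SDHB One Copy Deletion"))
#' is_inactivating(somatic_alteration("SDHA:c.511C>T (p.Arg171Cys)"))
is_inactivating <- function(a) {
  if (inherits(a, "somatic_alteration")) {
    if (a$kind == "NONE") return(FALSE)
    if (a$kind == "COPY_GAIN") return(FALSE)
    return(a$consequence %in% INACTIVATING_CONSEQUENCES)
  }
  if (inherits(a, "parsed_variant")) {
    return(consequence_class(a) %in% INACTIVATING_CONSEQUENCES)
  }
  stop("is_inactivating() expects a somatic_alteration or parsed_variant")
}

#' Construct a somatic alteration record
#'
#' Parses a somatic variant string and derives its consequence class and
#' inactivating status. `somatic_alteration(NULL)` or an empty string gives
#' the explicit "no alteration" record (`kind = "NONE"`).
#'
#' @param text Somatic variant string in the same dialect as
#'   [parse_variant_string()], or `NULL`/`""` for no alteration.
#' @return An object of class `somatic_alteration`: list with `gene`, `kind`,
#'   `hgvs_c`, `hgvs_p`, `consequence`, `inactivating`.
#' @export
somatic_alteration <- function(text = NULL) {
  if (is.null(text) || (is.character(text) && length(text) == 1L &&
                        (is.na(text) || !nzchar(trimws(text))))) {
    return(structure(list(gene = NA_character_, kind = "NONE",
                          hgvs_c = NA_character_, hgvs_p = NA_character_,
                          consequence = "UNKNOWN", inactivating = FALSE),
                     class = "somatic_alteration"))
  }
  pv <- parse_variant_string(text)
  cons <- consequence_class(pv)
  out <- structure(list(gene = pv$gene, kind = pv$kind,
                        hgvs_c = pv$cdna, hgvs_p = pv$protein,
                        consequence = cons, inactivating = FALSE),
                   class = "somatic_alteration")
  out$inactivating <- is_inactivating(out)
  out
}
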