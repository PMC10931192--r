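# The decision-table engine: the 19-scenario evidence framework encoded as
# data, a matcher returning exactly one scenario (or a not-accounted-for
# fallback), and machine verification of mutual exclusivity and reachability
# by exhaustive enumeration of the finite evidence space.

# printed-cell token -> internal vocabulary, per column family
CELL_TOKENS_TRISTATE <- c(Yes = "YES", No = "NO", "NA" = "NA")
CELL_TOKENS_KIT <- c(WT = "WT", "NA" = "NA", NOT_WT = "NOT_WT")
CELL_TOKENS_IHC <- c(Loss = "LOSS", Normal = "INTACT", "NA" = "NOT_TESTED",
                     Equivocal = "EQUIVOCAL")

#' Load the framework rulebook
#'
#' Reads the tabular rule encoding (one row per scenario; allowed-value cells
#' as pipe-separated tokens, e.g. `"Yes|No|NA"`) and returns a validated
#' rulebook. The packaged reference encoding has 19 rules: 5 for SDHA, 5 for
#' SDHB, 4 for SDHC and 5 for SDHD.
#'
#' Two matching modes are supported. `"STRICT"` matches the encoded cells
#' literally. `"LENIENT"` (the default) adds two relaxations: (a)
#' family-history, multifocality and metastasis cells that do not list "No"
#' additionally accept it, so a documented negative ancillary finding is not
#' treated as worse than an unascertained one; and (b) for genes other than
#' SDHA, a "Normal" SDHA-stain cell additionally accepts a not-performed SDHA
#' stain, since only SDHB loss is informative for those genes and SDHA
#' staining is usually run reflexively.
#'
#' @param source Path to the rule document; defaults to the packaged
#'   reference encoding.
#' @param mode `"LENIENT"` or `"STRICT"`.
#' @param version Version tag carried into logs and submission payloads.
#' @return Object of class `rulebook`.
#' @export
#' @examples
#' rb <- load_rulebook()
#' length(rb$rules)
load_rulebook <- function(source = NULL, mode = c("LENIENT", "STRICT"),
                          version = "table-1.0") {
  mode <- match.arg(mode)
  if (is.null(source)) {
    source <- system.file("extdata", "rulebook.tsv", package = "hppglintegrate")
  }
  if (!file.exists(source)) stop("rulebook document not found: ", source)
  tab <- utils::read.delim(source, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = NULL,
                           quote = "", check.names = FALSE)
  required <- c("code", "gene", EVIDENCE_COLUMNS, "category", "comment")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("rulebook document is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tab$code)) {
    stop("duplicate rule code(s): ",
         paste(unique(tab$code[duplicated(tab$code)]), collapse = ", "))
  }

  rules <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    if (!row$gene %in% SDH_GENES) {
      stop("rule ", row$code, ": unknown gene '", row$gene, "'")
    }
    if (!row$category %in% c("POSITIVE", "NEUTRAL", "NEGATIVE")) {
      stop("rule ", row$code, ": illegal category '", row$category, "'")
    }
    cells <- lapply(EVIDENCE_COLUMNS, function(col) {
      parse_rule_cell(row[[col]], col, row$code)
    })
    names(cells) <- EVIDENCE_COLUMNS
    structure(list(code = row$code, gene = row$gene, cells = cells,
                   category = row$category, comment = row$comment),
              class = "framework_rule")
  })
  names(rules) <- tab$code
  structure(list(rules = rules, mode = mode, version = version,
                 source = source),
            class = "rulebook")
}

# internal: one printed cell -> set of allowed internal values
parse_rule_cell <- function(cell, column, code) {
  if (is.na(cell) || !nzchar(trimws(cell))) {
    stop("rule ", code, ": empty cell in column '", column, "'")
  }
  tokens <- trimws(strsplit(cell, "|", fixed = TRUE)[[1]])
  dict <- if (column == "kit_pdgfra") CELL_TOKENS_KIT
          else if (column %in% c("ihc_sdha", "ihc_sdhb")) CELL_TOKENS_IHC
          else CELL_TOKENS_TRISTATE
  if (identical(tokens, "Any")) return(unname(dict))
  unknown <- setdiff(tokens, names(dict))
  if (length(unknown)) {
    stop("rule ", code, ", column '", column, "': unknown token(s) ",
         paste(unknown, collapse = ", "))
  }
  unname(dict[tokens])
}

# internal: allowed set for one column after applying the rulebook mode
effective_cell <- function(rule, column, mode) {
  cell <- rule$cells[[column]]
  if (mode == "LENIENT") {
    if (column %in% c("family_history", "multifocal", "metastasis") &&
        all(cell %in% c("YES", "NA"))) {
      cell <- union(cell, "NO")
    }
    if (column == "ihc_sdha" && rule$gene != "SDHA" &&
        identical(cell, "INTACT")) {
      cell <- c("INTACT", "NOT_TESTED")
    }
  }
  cell
}

#' @export
print.rulebook <- function(x, ...) {
  cat("<rulebook>", length(x$rules), "rules, mode", x$mode,
      ", version", x$version, "\n")
  genes <- vapply(x$rules, `[[`, character(1), "gene")
  print(table(factor(genes, levels = SDH_GENES)))
  invisible(x)
}

#' Match an evidence vector against the rulebook
#'
#' Evaluates, in table order, only the rules for the vector's gene and
#' returns the unique matching scenario's code, category and verbatim
#' comment. A vector carrying an additional germline variant in an
#' HPPGL-associated gene can never match (every scenario requires its
#' absence) and is returned as a no-match carrying the
#' `ADDITIONAL_GERMLINE` disqualifier. Any other unmatched combination is
#' returned as the not-accounted-for fallback.
#'
#' @param rb A [load_rulebook()] rulebook.
#' @param ev An [evidence_vector()].
#' @return Object of class `classification_result`: list with `matched_code`
#'   (rule code or `"NO_MATCH"`), `category` (`"POSITIVE"`, `"NEUTRAL"`,
#'   `"NEGATIVE"` or `"NOT_ACCOUNTED"`), `comment`, `disqualifiers`, and
#'   `evidence` (a copy of `ev`).
#' @export
#' @examples
#' rb <- load_rulebook()
#' ev <- evidence_vector("SDHA", additional_hppgl_germline = "NO",
#'   personal_history = "NO", family_history = "NO", multifocal = "NO",
#'   metastasis = "NO", somatic_inactivating = "NO", kit_pdgfra = "WT",
#'   ihc_sdha = "INTACT", ihc_sdhb = "INTACT")
#' match_rule(rb, ev)$matched_code
match_rule <- function(rb, ev) {
  stopifnot(inherits(rb, "rulebook"), inherits(ev, "evidence_vector"))
  probs <- validate_evidence(ev)
  if (length(probs)) stop("invalid evidence vector: ", paste(probs, collapse = "; "))

  result <- function(code, category, comment, disq = character()) {
    structure(list(matched_code = code, category = category, comment = comment,
                   disqualifiers = disq, evidence = ev),
              class = "classification_result")
  }

  if (ev$additional_hppgl_germline == "YES") {
    return(result(NO_MATCH, "NOT_ACCOUNTED",
                  paste("This combination of evidence is not currently",
                        "accounted for: an additional germline variant in an",
                        "HPPGL-associated gene precludes framework assessment."),
                  disq = "ADDITIONAL_GERMLINE"))
  }

  hits <- list()
  for (rule in rb$rules) {
    if (rule$gene != ev$gene) next
    match <- all(vapply(EVIDENCE_COLUMNS, function(col) {
      ev[[col]] %in% effective_cell(rule, col, rb$mode)
    }, logical(1)))
    if (match) hits[[length(hits) + 1L]] <- rule
  }
  if (length(hits) > 1L) {
    stop("internal consistency failure: evidence vector matches rules ",
         paste(vapply(hits, `[[`, character(1), "code"), collapse = ", "))
  }
  if (length(hits) == 1L) {
    r <- hits[[1L]]
    return(result(r$code, r$category, r$comment))
  }
  result(NO_MATCH, "NOT_ACCOUNTED",
         paste("This combination of evidence is not currently accounted for",
               "within the variant evidence framework."))
}

#' @export
print.classification_result <- function(x, ...) {
  cat("<classification_result>", x$matched_code, "/", x$category, "\n")
  if (length(x$disqualifiers)) cat("  disqualifiers:",
                                   paste(x$disqualifiers, collapse = ", "), "\n")
  cat(" ", strwrap(x$comment, width = 76, exdent = 2), sep = "\n")
  invisible(x)
}

# internal: the full finite evidence grid (one data.frame, character columns)
evidence_grid <- function() {
  grid <- expand.grid(evidence_domains(), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid
}

# internal: logical match vector of one rule over the grid
rule_match_matrix <- function(rule, grid, mode) {
  ok <- rep(TRUE, nrow(grid))
  for (col in EVIDENCE_COLUMNS) {
    ok <- ok & grid[[col]] %in% effective_cell(rule, col, mode)
  }
  ok
}

#' Verify mutual exclusivity of the rulebook
#'
#' Exhaustively enumerates the finite evidence space for each gene (the
#' product of all column domains) and reports every vector that matches more
#' than one rule. The reference encoding is expected to produce an empty
#' report in both matching modes; the matcher relies on this to return a
#' unique scenario.
#'
#' @param rb A rulebook.
#' @return Data frame with columns `gene`, `rule_a`, `rule_b`, `n_overlap`
#'   (zero rows when the rulebook is exclusive). The number of vectors
#'   enumerated per gene is attached as attribute `n_space`.
#' @export
check_exclusivity <- function(rb) {
  stopifnot(inherits(rb, "rulebook"))
  grid <- evidence_grid()
  out <- list()
  for (g in SDH_GENES) {
    rules <- Filter(function(r) r$gene == g, rb$rules)
    if (length(rules) < 2L) next
    matches <- lapply(rules, rule_match_matrix, grid = grid, mode = rb$mode)
    codes <- vapply(rules, `[[`, character(1), "code")
    for (i in seq_along(rules)) {
      for (j in seq_along(rules)) {
        if (j <= i) next
        n <- sum(matches[[i]] & matches[[j]])
        if (n > 0L) {
          out[[length(out) + 1L]] <- data.frame(
            gene = g, rule_a = codes[i], rule_b = codes[j], n_overlap = n,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  report <- if (length(out)) do.call(rbind, out) else
    data.frame(gene = character(), rule_a = character(),
               rule_b = character(), n_overlap = integer(),
               stringsAsFactors = FALSE)
  attr(report, "n_space") <- nrow(grid)
  report
}

#' Count satisfying evidence vectors per rule
#'
#' Enumerates the finite evidence space and counts, for each rule, how many
#' vectors it matches. A count of zero marks a dead (unreachable) scenario.
#'
#' @param rb A rulebook.
#' @return Data frame with columns `code`, `gene`, `category`, `n_satisfying`.
#' @export
enumerate_reachable <- function(rb) {
  stopifnot(inherits(rb, "rulebook"))
  grid <- evidence_grid()
  data.frame(
    code = vapply(rb$rules, `[[`, character(1), "code"),
    gene = vapply(rb$rules, `[[`, character(1), "gene"),
    category = vapply(rb$rules, `[[`, character(1), "category"),
    n_satisfying = vapply(rb$rules, function(r)
      sum(rule_match_matrix(r, grid, rb$mode)), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
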