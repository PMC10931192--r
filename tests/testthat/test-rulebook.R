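test_that("the reference encoding loads with 19 gene-grouped rules", {
  rb <- load_rulebook()
  expect_identical(length(rb$rules), 19L)
  genes <- vapply(rb$rules, `[[`, character(1), "gene")
  expect_identical(as.integer(table(factor(genes, levels = sdh_genes()))),
                   c(5L, 5L, 4L, 5L))
  cats <- vapply(rb$rules, `[[`, character(1), "category")
  expect_true(all(cats %in% c("POSITIVE", "NEUTRAL", "NEGATIVE")))
  expect_true(all(nzchar(vapply(rb$rules, `[[`, character(1), "comment"))))
})

test_that("malformed rule documents are rejected with the offender named", {
  src <- system.file("extdata", "rulebook.tsv", package = "hppglintegrate")
  tab <- read.delim(src, colClasses = "character", na.strings = NULL,
                    quote = "", check.names = FALSE)

  dup <- rbind(tab, tab[1, ])
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write.table(dup, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_rulebook(f1), "A-I")

  f2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab[, setdiff(names(tab), "paternal_inheritance")], f2,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_rulebook(f2), "paternal_inheritance")

  tab3 <- tab
  tab3$family_history[3] <- ""
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab3, f3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_rulebook(f3), "family_history")

  tab4 <- tab
  tab4$metastasis[1] <- "Sometimes"
  f4 <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab4, f4, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_rulebook(f4), "metastasis")
})

test_that("the all-negative worked-up vector is NEGATIVE for every gene", {
  rb <- load_rulebook()
  expected <- c(SDHA = "A-V", SDHB = "B-IV", SDHC = "C-IV", SDHD = "D-IV")
  for (gene in sdh_genes()) {
    res <- match_rule(rb, all_negative_evidence(gene))
    expect_identical(res$matched_code, unname(expected[gene]))
    expect_identical(res$category, "NEGATIVE")
    expect_identical(res$comment, rb$rules[[expected[gene]]]$comment)
  }
})

test_that("concordant positive evidence matches the POSITIVE scenario", {
  rb <- load_rulebook()
  ev <- evidence_vector("SDHB",
                        additional_hppgl_germline = "NO",
                        personal_history = "YES",
                        paternal_inheritance = "NA",
                        family_history = "YES",
                        multifocal = "YES",
                        metastasis = "YES",
                        somatic_inactivating = "YES",
                        kit_pdgfra = "WT",
                        ihc_sdha = "INTACT",
                        ihc_sdhb = "LOSS")
  res <- match_rule(rb, ev)
  expect_identical(res$matched_code, "B-I")
  expect_identical(res$category, "POSITIVE")
  expect_match(res$comment, "support the likely relevance of this SDHB variant",
               fixed = TRUE)
})

test_that("unmatched combinations fall back to the not-accounted message", {
  rb <- load_rulebook()
  # personal history with SDHB loss but no somatic second hit is not a
  # scenario in the framework
  ev <- evidence_vector("SDHB",
                        additional_hppgl_germline = "NO",
                        personal_history = "YES",
                        family_history = "NO", multifocal = "NO",
                        metastasis = "NO", somatic_inactivating = "NO",
                        kit_pdgfra = "WT", ihc_sdha = "INTACT",
                        ihc_sdhb = "LOSS")
  res <- match_rule(rb, ev)
  expect_identical(res$matched_code, "NO_MATCH")
  expect_identical(res$category, "NOT_ACCOUNTED")
  expect_match(res$comment, "not currently accounted for")
})

test_that("an additional qualifying germline variant disqualifies matching", {
  rb <- load_rulebook()
  ev <- all_negative_evidence("SDHA")
  ev$additional_hppgl_germline <- "YES"
  res <- match_rule(rb, ev)
  expect_identical(res$matched_code, "NO_MATCH")
  expect_identical(res$category, "NOT_ACCOUNTED")
  expect_identical(res$disqualifiers, "ADDITIONAL_GERMLINE")
})

test_that("rules are mutually exclusive over the whole evidence space", {
  for (mode in c("STRICT", "LENIENT")) {
    rb <- load_rulebook(mode = mode)
    report <- check_exclusivity(rb)
    expect_identical(nrow(report), 0L, info = mode)
    expect_gte(attr(report, "n_space"), 3^7 * 3 * 4 * 4)
  }
})

test_that("matching agrees with an independent per-vector evaluation", {
  # independent oracle: brute-force cell membership per rule on sampled
  # vectors, compared against match_rule (which also enforces uniqueness)
  rb <- load_rulebook()
  doms <- evidence_domains()
  withr::with_seed(402, {
    for (rep in seq_len(300)) {
      gene <- sample(sdh_genes(), 1L)
      vals <- lapply(doms, sample, size = 1L)
      ev <- do.call(evidence_vector, c(list(gene = gene), vals))
      res <- match_rule(rb, ev)
      if (ev$additional_hppgl_germline == "YES") {
        expect_identical(res$matched_code, "NO_MATCH")
        next
      }
      hits <- character()
      for (rule in rb$rules) {
        if (rule$gene != gene) next
        cells_ok <- TRUE
        for (col in names(doms)) {
          cell <- rule$cells[[col]]
          if (rb$mode == "LENIENT") {
            if (col %in% c("family_history", "multifocal", "metastasis") &&
                !"NO" %in% cell) cell <- c(cell, "NO")
            if (col == "ihc_sdha" && rule$gene != "SDHA" &&
                identical(cell, "INTACT")) cell <- c(cell, "NOT_TESTED")
          }
          if (!ev[[col]] %in% cell) { cells_ok <- FALSE; break }
        }
        if (cells_ok) hits <- c(hits, rule$code)
      }
      expect_lte(length(hits), 1L)
      expect_identical(res$matched_code,
                       if (length(hits)) hits else "NO_MATCH")
    }
  })
})

test_that("every scenario is reachable and a constructed collision is caught", {
  for (mode in c("STRICT", "LENIENT")) {
    rb <- load_rulebook(mode = mode)
    reach <- enumerate_reachable(rb)
    expect_identical(nrow(reach), 19L)
    expect_true(all(reach$n_satisfying >= 1), info = mode)
  }
  # widening A-IV's SDHB stain cell to accept Loss collides with A-II
  rb <- load_rulebook()
  rb$rules[["A-IV"]]$cells$ihc_sdhb <- c("INTACT", "LOSS")
  report <- check_exclusivity(rb)
  expect_true(any(report$rule_a == "A-II" & report$rule_b == "A-IV"))

  # a single-rule book has exactly one positive count
  rb1 <- rb
  rb1$rules <- rb$rules["A-I"]
  reach1 <- enumerate_reachable(rb1)
  expect_identical(nrow(reach1), 1L)
  expect_gte(reach1$n_satisfying, 1)
})

test_that("matching is a pure function of rulebook, mode and evidence", {
  rb <- load_rulebook()
  ev <- all_negative_evidence("SDHC")
  r1 <- match_rule(rb, ev)
  r2 <- match_rule(rb, ev)
  expect_identical(r1$matched_code, r2$matched_code)
  expect_identical(r1$comment, r2$comment)
  # the returned evidence snapshot is a faithful copy
  expect_identical(r1$evidence, ev)
})
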