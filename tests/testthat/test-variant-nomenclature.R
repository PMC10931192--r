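test_that("the clinical variant-string dialect parses field by field", {
  cases <- list(
    list(text = "SDHC:c.397C>T (p.Arg133Ter)", gene = "SDHC",
         cdna = "c.397C>T", protein = "p.Arg133Ter", kind = "SNV"),
    list(text = "SDHB One Copy Deletion", gene = "SDHB",
         cdna = NA_character_, protein = NA_character_, kind = "COPY_LOSS"),
    list(text = "SDHA EX1_9 Del", gene = "SDHA",
         cdna = NA_character_, protein = NA_character_, kind = "EXON_DELETION"),
    list(text = "SDHB EX8_3'UTR Del", gene = "SDHB",
         cdna = NA_character_, protein = NA_character_, kind = "EXON_DELETION"),
    list(text = "SDHA Copy Number Gain (<6 copies)", gene = "SDHA",
         cdna = NA_character_, protein = NA_character_, kind = "COPY_GAIN"),
    list(text = "SDHC Gain (estimated 8 copies)", gene = "SDHC",
         cdna = NA_character_, protein = NA_character_, kind = "COPY_GAIN"),
    list(text = "SDHB Duplication", gene = "SDHB",
         cdna = NA_character_, protein = NA_character_, kind = "DUPLICATION"),
    list(text = "SDHC:c.-30-?_2318+?dup", gene = "SDHC",
         cdna = "c.-30-?_2318+?dup", protein = NA_character_,
         kind = "DUPLICATION"),
    list(text = "SDHB:159_184delIns25 (p.Gly53fs)", gene = "SDHB",
         cdna = "c.159_184delIns25", protein = "p.Gly53fs", kind = "INDEL"),
    list(text = "SDHB:c.605_609dupACGGA (p.Asp204fs)", gene = "SDHB",
         cdna = "c.605_609dupACGGA", protein = "p.Asp204fs", kind = "INDEL"),
    list(text = "SDHC:c.397C>T(p.Arg133Ter)", gene = "SDHC",
         cdna = "c.397C>T", protein = "p.Arg133Ter", kind = "SNV"))
  for (case in cases) {
    pv <- parse_variant_string(case$text)
    expect_true(pv$ok, info = case$text)
    expect_identical(pv$gene, case$gene, info = case$text)
    expect_identical(pv$cdna, case$cdna, info = case$text)
    expect_identical(pv$protein, case$protein, info = case$text)
    expect_identical(pv$kind, case$kind, info = case$text)
  }
})

test_that("unparseable input yields a failure descriptor, never an error", {
  for (bad in list("", "   ", NA_character_, "???", "c.397C>T", 42)) {
    pv <- parse_variant_string(bad)
    expect_false(pv$ok)
    expect_identical(pv$kind, "UNKNOWN")
    expect_true(nzchar(pv$message))
  }
})

test_that("consequence classification follows HGVS notation", {
  cases <- c("SDHC:c.397C>T (p.Arg133Ter)" = "NONSENSE",
             "SDHA:c.688delG (p.Glu230fs)" = "FRAMESHIFT",
             "SDHA:c.1043_1055del (p.Thr348LysfsTer37)" = "FRAMESHIFT",
             "SDHA:c.1794+1G>A" = "CANONICAL_SPLICE",
             "SDHA:c.1432+1G>C" = "CANONICAL_SPLICE",
             "SDHB:c.72+1G>T" = "CANONICAL_SPLICE",
             "SDHA:c.1908+6T>C" = "INTRONIC_OTHER",
             "SDHB:c.200+3G>C" = "INTRONIC_OTHER",
             "SDHA:c.622-7C>T" = "INTRONIC_OTHER",
             "SDHA:c.511C>T (p.Arg171Cys)" = "MISSENSE",
             "SDHD:c.400T>G (p.L134V)" = "MISSENSE",
             "RET:c.405C>T (p.Gly135=)" = "SYNONYMOUS",
             "SDHB:c.478_480del (p.Lys160del)" = "INFRAME_INDEL",
             "SDHB One Copy Deletion" = "COPY_LOSS",
             "SDHA Copy Number Gain (<6 copies)" = "COPY_GAIN",
             "SDHA EX1_9 Del" = "STRUCTURAL_DISRUPTIVE",
             "SDHB Duplication" = "UNKNOWN")
  for (text in names(cases)) {
    expect_identical(consequence_class(parse_variant_string(text)),
                     unname(cases[[text]]), info = text)
  }
})

test_that("inactivating-allele determination implements the two-hit taxonomy", {
  expect_true(is_inactivating(somatic_alteration("SDHA:c.1432+1G>C")))
  expect_true(is_inactivating(somatic_alteration("SDHB One Copy Deletion")))
  expect_true(is_inactivating(somatic_alteration("SDHA:c.1534C>T (p.Arg512Ter)")))
  # copy gains are a third state: never a second hit
  expect_false(is_inactivating(somatic_alteration("SDHA Copy Number Gain (<6 copies)")))
  # somatic missense is never a second hit
  expect_false(is_inactivating(somatic_alteration("SDHA:c.511C>T (p.Arg171Cys)")))
  expect_false(is_inactivating(somatic_alteration(NULL)))
  expect_false(is_inactivating(somatic_alteration("SDHC:c.-30-?_2318+?dup")))
})

test_that("consequence classification is stable under parse-format-parse", {
  texts <- unlist(lapply(c("T4", "T5", "T6", "T7", "T8"), function(id) {
    recs <- load_fixture(id)
    unlist(lapply(recs, function(r) c(
      vapply(r$germline_variants, `[[`, character(1), "text"),
      vapply(r$other_germline, `[[`, character(1), "text"))))
  }))
  for (text in texts) {
    pv <- parse_variant_string(text)
    expect_true(pv$ok, info = text)
    pv2 <- parse_variant_string(format_variant(pv))
    expect_identical(consequence_class(pv2), consequence_class(pv), info = text)
    expect_identical(pv2$kind, pv$kind, info = text)
    expect_identical(pv2$gene, pv$gene, info = text)
  }
})
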