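test_that("fixture tables read with the published record counts", {
  expect_length(load_fixture("T4"), 37L)
  expect_length(load_fixture("T5"), 40L)
  expect_length(load_fixture("T6"), 15L)
  expect_length(load_fixture("T7"), 10L)
  expect_length(load_fixture("T8"), 7L)
  expect_error(load_fixture("T9"), "unknown fixture")
})

test_that("a header-only table yields an empty cohort; unknown columns warn", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("subject_id", "cohort", "germline_variants"),
                   collapse = "\t"), f)
  expect_length(read_cohort_table(f), 0L)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject_id\tshoe_size", "A\t43"), f2)
  expect_warning(recs <- read_cohort_table(f2), "shoe_size")
  expect_length(recs, 1L)
  # missing columns become not-ascertained, never negative
  expect_identical(recs[[1]]$clinical$personal_pgl_pcc, "NA")
  expect_identical(recs[[1]]$ihc_sdhb, "NOT_TESTED")
})

test_that("evidence derivation maps record fields onto the framework columns", {
  t4 <- load_fixture("T4")

  ev93 <- derive_evidence(fixture_subject(t4, "93"))
  expect_identical(ev93$gene, "SDHD")
  expect_identical(ev93$personal_history, "YES")
  expect_identical(ev93$paternal_inheritance, "YES")
  expect_identical(ev93$family_history, "YES")
  expect_identical(ev93$somatic_inactivating, "YES")
  expect_identical(ev93$kit_pdgfra, "WT")
  expect_identical(ev93$ihc_sdhb, "LOSS")
  expect_identical(ev93$ihc_sdha, "NOT_TESTED")

  # a second qualifying germline variant flips the disqualifier column
  expect_identical(derive_evidence(fixture_subject(t4, "63"))$additional_hppgl_germline,
                   "YES")
  expect_identical(derive_evidence(fixture_subject(t4, "33"))$additional_hppgl_germline,
                   "NO")

  # the second hit is gene-scoped: subject 63's somatic SDHA frameshift is
  # not a hit for the germline SDHB variant, but its SDHB copy loss is
  rec63 <- fixture_subject(t4, "63")
  rec63$somatic_alterations <- Filter(function(a) a$gene == "SDHA",
                                      rec63$somatic_alterations)
  expect_identical(derive_evidence(rec63)$somatic_inactivating, "NO")

  # germline-only evidence: all clinical defaults NA, somatic NA
  bare <- patient_record("B1", cohort = "GERMLINE_ONLY",
                         germline_variants = list(
                           germline_variant("SDHA:c.91C>T (p.Arg31Ter)", "PATHOGENIC")),
                         other_germline_assessed = FALSE,
                         somatic_assessed = FALSE)
  evb <- derive_evidence(bare)
  for (col in c("additional_hppgl_germline", "personal_history",
                "family_history", "multifocal", "metastasis",
                "somatic_inactivating", "kit_pdgfra")) {
    expect_identical(evb[[col]], "NA", info = col)
  }

  expect_error(derive_evidence(patient_record("T", cohort = "TUMOR_ONLY")),
               "no assessable")
})

test_that("the integrated-cohort summary reproduces the reference counts", {
  s4 <- summarize_cohort(load_fixture("T4"))
  expect_identical(s4$n_records, 37L)
  expect_identical(s4$n_plp, 37L)
  expect_identical(s4$n_personal_history, 16L)
  expect_identical(s4$n_family_history, 5L)
  expect_identical(s4$n_somatic_inactivating, 13L)
  expect_identical(s4$n_copy_loss_second_hit, 11L)
  expect_identical(s4$n_snv_second_hit, 2L)
  expect_identical(s4$n_no_somatic_alteration, 23L)
  expect_identical(s4$n_ihc_concordant_among_second_hit, 8L)
  expect_identical(as.integer(s4$per_gene),  c(10L, 13L, 13L, 1L))
  # conservation: hits + gains + negatives account for every record
  expect_identical(s4$n_somatic_inactivating + s4$n_no_somatic_alteration + 1L,
                   s4$n_records)

  s5 <- summarize_cohort(load_fixture("T5"))
  expect_identical(s5$n_personal_history, 4L)
  expect_identical(s5$n_somatic_inactivating, 0L)
  expect_identical(s5$n_family_history, 0L)

  s6 <- summarize_cohort(load_fixture("T6"))
  expect_identical(s6$n_personal_history, 1L)

  s0 <- summarize_cohort(list())
  expect_identical(s0$n_records, 0L)
  expect_identical(s0$n_plp, 0L)
  expect_identical(s0$n_somatic_inactivating, 0L)
})

test_that("batch classification is complete, idempotent and order-invariant", {
  rb <- load_rulebook()
  t4 <- load_fixture("T4")
  res <- classify_batch(t4, rb)
  kb <- res$knowledgebase
  expect_identical(nrow(kb), 37L)
  expect_true(all(kb$code == "NO_MATCH" |
                    kb$code %in% names(rb$rules)))
  expect_true(all(kb$category %in% c("POSITIVE", "NEUTRAL", "NEGATIVE",
                                     "NOT_ACCOUNTED")))
  expect_identical((kb$code == "NO_MATCH"),
                   (kb$category == "NOT_ACCOUNTED"))
  # one log line per processed variant, plus the run header
  expect_identical(length(res$log), 38L)
  expect_match(res$log[1], "^# rulebook")

  # re-matching each stored evidence snapshot reproduces the same code
  expect_identical(reclassify_snapshots(kb, rb), kb$code)

  # shuffling the input never changes any per-subject result
  withr::with_seed(77, {
    shuffled <- sample(t4)
  })
  kb2 <- classify_batch(shuffled, rb)$knowledgebase
  ord <- order(kb$subject_id)
  ord2 <- order(kb2$subject_id)
  expect_identical(kb2$code[ord2], kb$code[ord])
  expect_identical(kb2$category[ord2], kb$category[ord])

  # no record of the SDHB VUS table reaches POSITIVE
  kb6 <- classify_batch(load_fixture("T6"), rb)$knowledgebase
  expect_identical(nrow(kb6), 15L)
  expect_identical(sum(kb6$category == "POSITIVE"), 0L)

  empty <- classify_batch(list(), rb)
  expect_null(empty$knowledgebase)
  expect_identical(length(empty$log), 1L)
})

test_that("the germline/tumor merge partitions subjects by data availability", {
  g <- data.frame(subject_id = c("a", "b", "c"),
                  germline_variants = "SDHB:c.137G>A (p.Arg46Gln)",
                  stringsAsFactors = FALSE)
  t <- data.frame(subject_id = c("b", "c", "d", "e"),
                  somatic_alterations = "Neg", stringsAsFactors = FALSE)
  m <- merge_isgd(g, t)
  expect_identical(unname(m$partition),
                   c(2L, 1L, 2L))
  expect_identical(sort(m$table$subject_id[m$table$cohort == "GERMLINE_AND_TUMOR"]),
                   c("b", "c"))

  # disjoint id sets: no integrated subjects
  m2 <- merge_isgd(data.frame(subject_id = "x", stringsAsFactors = FALSE),
                   data.frame(subject_id = "y", stringsAsFactors = FALSE))
  expect_identical(unname(m2$partition["GERMLINE_AND_TUMOR"]), 0L)

  # duplicate ids within one source are an error
  expect_error(merge_isgd(data.frame(subject_id = c("x", "x")), t), "duplicate")

  # conflicting shared fields are reported, not overwritten
  g3 <- data.frame(subject_id = "a", ihc_sdhb = "Loss", stringsAsFactors = FALSE)
  t3 <- data.frame(subject_id = "a", ihc_sdhb = "Intact", stringsAsFactors = FALSE)
  m3 <- merge_isgd(g3, t3)
  expect_identical(nrow(m3$conflicts), 1L)
  expect_identical(m3$conflicts$column, "ihc_sdhb")
  expect_identical(m3$table$ihc_sdhb, "Loss")
})

test_that("generated sources merge back into the generated partition", {
  params <- synthetic_cohort_params(seed = 515, scale = 20)
  src <- generate_isgd_sources(params)
  m <- merge_isgd(src$germline, src$tumor)
  expect_equal(unname(m$partition),
               c(round(109 / 20), round(494 / 20), round(7997 / 20)))
  expect_identical(nrow(m$conflicts), 0L)
  # merged table reads back as classifiable records
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(m$table, f, sep = "\t", quote = FALSE, row.names = FALSE)
  recs <- read_cohort_table(f)
  expect_length(recs, sum(m$partition))
})
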