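# Shared builders for compact test records.

make_record <- function(subject_id = "X1",
                        germline = "SDHB:c.137G>A (p.Arg46Gln)",
                        classification = "PATHOGENIC",
                        cohort = "GERMLINE_AND_TUMOR",
                        somatic = character(),
                        personal = "NO", gist = FALSE, family = "NO",
                        multifocal = "NO", metastasis = "NO",
                        parent = "NOT_TESTED",
                        kit = "WT", pdgfra = "WT",
                        ihc_sdha = "NOT_TESTED", ihc_sdhb = "NOT_TESTED",
                        other = character(),
                        somatic_assessed = TRUE) {
  patient_record(
    subject_id = subject_id, cohort = cohort,
    germline_variants = lapply(germline, germline_variant,
                               classification = classification),
    other_germline = lapply(other, germline_variant),
    other_germline_assessed = TRUE,
    somatic_alterations = lapply(somatic, somatic_alteration),
    somatic_assessed = somatic_assessed,
    clinical = clinical_history(
      personal_pgl_pcc = personal, personal_with_gist = gist,
      parent_of_origin = parent, family_pgl_pcc_gist = family,
      multifocal_extra_adrenal = multifocal, metastasis = metastasis),
    driver_status = driver_gene_status(kit = kit, pdgfra = pdgfra),
    ihc_sdha = ihc_sdha, ihc_sdhb = ihc_sdhb)
}

# the all-negative evidence vector for a gene (fully worked-up, no findings)
all_negative_evidence <- function(gene) {
  evidence_vector(gene,
                  additional_hppgl_germline = "NO",
                  personal_history = "NO",
                  paternal_inheritance = "NO",
                  family_history = "NO",
                  multifocal = "NO",
                  metastasis = "NO",
                  somatic_inactivating = "NO",
                  kit_pdgfra = "WT",
                  ihc_sdha = "INTACT",
                  ihc_sdhb = "INTACT")
}

fixture_subject <- function(records, id) {
  records[[which(vapply(records, `[[`, character(1), "subject_id") == id)]]
}
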