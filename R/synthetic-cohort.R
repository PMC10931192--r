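# Seeded synthetic-cohort generator emulating the three-cohort study
# structure: a fully integrated germline+tumor cohort, a germline-only
# cohort, and a tumor-only cohort. Default parameters are the empirical
# fractions observed in the packaged reference fixtures; the generator is
# the package's instrument for scale testing and statistical validation of
# the pipeline, not a model of real HPPGL biology (see the vignette).

#' Synthetic cohort parameters
#'
#' Defaults reproduce the observed structure of the reference cohorts: the
#' published cohort sizes (109 integrated / 494 germline-only / 7997
#' tumor-only, scalable by `scale`), the germline gene mix of the 109
#' integrated records, the 37/109 pathogenic fraction, and the
#' class-conditional rates observed among the 37 pathogenic and 72 VUS
#' integrated records (personal history 16/37 and 5/72; family history 5/37;
#' same-gene second hit 13/37 and 1/72, split 11/13 copy-loss; gene-concordant
#' IHC 8/13 given a hit; incidental copy-number gain 1/37; KIT/PDGFRA
#' mutation 2/109; additional qualifying germline variant 7/109).
#'
#' @param n_cohort1,n_cohort2,n_cohort3 Cohort sizes before scaling.
#' @param scale Down-scaling divisor for desk-scale runs (sizes are
#'   `round(n / scale)`).
#' @param gene_freq Named probability vector over the four SDHx genes.
#' @param frac_plp Fraction of germline records classified P/LP.
#' @param p_personal_plp,p_personal_vus Probability of positive personal
#'   history given classification.
#' @param p_family_plp,p_family_vus Probability of positive family history.
#' @param p_second_hit_plp,p_second_hit_vus Probability of a same-gene
#'   somatic inactivating allele.
#' @param p_copy_loss_given_hit Probability the second hit is a one-copy
#'   loss (otherwise an inactivating SNV).
#' @param p_ihc_concordant_given_hit Probability of a gene-concordant IHC
#'   loss pattern given a second hit.
#' @param p_copy_gain Probability of an incidental (non-inactivating)
#'   copy-number gain when there is no second hit.
#' @param p_kit_pdgfra_mut Probability of a KIT or PDGFRA mutation.
#' @param p_paternal_plp Probability a pathogenic SDHD variant is recorded
#'   as paternally inherited.
#' @param p_additional_germline Probability of an additional qualifying
#'   germline variant.
#' @param p_multifocal,p_metastasis Marginal probabilities of the ancillary
#'   tumor findings.
#' @param seed Mandatory integer seed; generation is deterministic given it.
#' @return Object of class `synthetic_cohort_params` (a validated list).
#' @export
synthetic_cohort_params <- function(n_cohort1 = 109, n_cohort2 = 494,
                                    n_cohort3 = 7997, scale = 1,
                                    gene_freq = c(SDHA = 49, SDHB = 29,
                                                  SDHC = 23, SDHD = 8) / 109,
                                    frac_plp = 37 / 109,
                                    p_personal_plp = 16 / 37,
                                    p_personal_vus = 5 / 72,
                                    p_family_plp = 5 / 37,
                                    p_family_vus = 0,
                                    p_second_hit_plp = 13 / 37,
                                    p_second_hit_vus = 1 / 72,
                                    p_copy_loss_given_hit = 11 / 13,
                                    p_ihc_concordant_given_hit = 8 / 13,
                                    p_copy_gain = 1 / 37,
                                    p_kit_pdgfra_mut = 2 / 109,
                                    p_paternal_plp = 1,
                                    p_additional_germline = 7 / 109,
                                    p_multifocal = 1 / 109,
                                    p_metastasis = 5 / 109,
                                    seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("a single integer seed is mandatory for reproducibility")
  }
  params <- list(n_cohort1 = n_cohort1, n_cohort2 = n_cohort2,
                 n_cohort3 = n_cohort3, scale = scale, gene_freq = gene_freq,
                 frac_plp = frac_plp,
                 p_personal_plp = p_personal_plp,
                 p_personal_vus = p_personal_vus,
                 p_family_plp = p_family_plp, p_family_vus = p_family_vus,
                 p_second_hit_plp = p_second_hit_plp,
                 p_second_hit_vus = p_second_hit_vus,
                 p_copy_loss_given_hit = p_copy_loss_given_hit,
                 p_ihc_concordant_given_hit = p_ihc_concordant_given_hit,
                 p_copy_gain = p_copy_gain,
                 p_kit_pdgfra_mut = p_kit_pdgfra_mut,
                 p_paternal_plp = p_paternal_plp,
                 p_additional_germline = p_additional_germline,
                 p_multifocal = p_multifocal, p_metastasis = p_metastasis,
                 seed = as.integer(seed))
  probs <- params[grep("^(p_|frac_)", names(params))]
  bad <- names(probs)[vapply(probs, function(p)
    !is.numeric(p) || any(p < 0 | p > 1), logical(1))]
  if (length(bad)) stop("probabilities outside [0,1]: ", paste(bad, collapse = ", "))
  if (abs(sum(gene_freq) - 1) > 1e-8 || !setequal(names(gene_freq), SDH_GENES)) {
    stop("gene_freq must be a probability vector over ",
         paste(SDH_GENES, collapse = ", "))
  }
  if (any(c(n_cohort1, n_cohort2, n_cohort3) < 0) || scale <= 0) {
    stop("cohort sizes must be non-negative and scale positive")
  }
  structure(params, class = "synthetic_cohort_params")
}

# internal: evaluate code under a private, restored RNG stream
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(code)
}

#' Generate a seeded synthetic cohort
#'
#' Draws patient records with the statistical structure described by
#' `params`. Cohort-1-style records carry germline, clinical, tumor and IHC
#' fields; germline-only records carry no tumor data (somatic status not
#' ascertained); tumor-only records carry a somatic SDHx alteration and no
#' germline or clinical-genetics evaluation. Generation is deterministic
#' given `params$seed` and every record passes [validate_record()].
#'
#' @param params A [synthetic_cohort_params()] object.
#' @param cohorts Which cohorts to generate (default: all three).
#' @return List of `patient_record` objects.
#' @export
generate_cohort <- function(params, cohorts = COHORT_LEVELS) {
  stopifnot(inherits(params, "synthetic_cohort_params"))
  cohorts <- match.arg(cohorts, COHORT_LEVELS, several.ok = TRUE)
  sizes <- c(GERMLINE_AND_TUMOR = round(params$n_cohort1 / params$scale),
             GERMLINE_ONLY = round(params$n_cohort2 / params$scale),
             TUMOR_ONLY = round(params$n_cohort3 / params$scale))
  with_local_seed(params$seed, {
    recs <- list()
    serial <- 0L
    for (co in COHORT_LEVELS) {       # fixed draw order keeps streams stable
      if (!co %in% cohorts) next
      n <- sizes[[co]]
      if (n <= 0) next
      for (i in seq_len(n)) {
        serial <- serial + 1L
        id <- sprintf("SYN-%s-%05d", substr(co, 1, 1), serial)
        recs[[length(recs) + 1L]] <- synth_record(id, co, params)
      }
    }
    recs
  })
}

# internal: one synthetic record
synth_record <- function(id, cohort, params) {
  bern <- function(p) stats::runif(1) < p

  if (cohort == "TUMOR_ONLY") {
    gene <- sample(names(params$gene_freq), 1L, prob = params$gene_freq)
    pos <- sample(100:1500, 1L)
    kind_draw <- stats::runif(1)
    som_text <- if (kind_draw < 0.15) paste(gene, "One Copy Deletion")
      else if (kind_draw < 0.20) paste(gene, "Copy Number Gain")
      else sprintf("%s:c.%dG>A (p.Gly%dAsp)", gene, pos, ceiling(pos / 3))
    return(patient_record(
      subject_id = id, cohort = cohort,
      somatic_alterations = list(somatic_alteration(som_text)),
      somatic_assessed = TRUE,
      clinical = clinical_history(),            # not evaluated: all NA
      driver_status = driver_gene_status(
        kit = if (bern(params$p_kit_pdgfra_mut)) "MUTATED" else "WT",
        pdgfra = "WT")))
  }

  gene <- sample(names(params$gene_freq), 1L, prob = params$gene_freq)
  plp <- bern(params$frac_plp)
  aa <- sample(20:450, 1L)
  germ_text <- if (plp) {
    sprintf("%s:c.%dC>T (p.Arg%dTer)", gene, 3L * aa - 2L, aa)
  } else {
    sprintf("%s:c.%dG>A (p.Gly%dAsp)", gene, 3L * aa - 2L, aa)
  }
  cls <- if (plp) "PATHOGENIC" else "VUS"

  personal <- bern(if (plp) params$p_personal_plp else params$p_personal_vus)
  family <- bern(if (plp) params$p_family_plp else params$p_family_vus)
  multifocal <- bern(params$p_multifocal)
  metastasis <- bern(params$p_metastasis)
  additional <- bern(params$p_additional_germline)
  other <- if (additional) list(germline_variant("VHL:c.499C>T (p.Arg167Trp)"))
           else list()
  parent <- if (gene == "SDHD" && plp && bern(params$p_paternal_plp))
    "PATERNAL" else "NOT_TESTED"

  clinical <- clinical_history(
    personal_pgl_pcc = if (personal) "YES" else "NO",
    personal_with_gist = FALSE,
    parent_of_origin = parent,
    family_pgl_pcc_gist = if (family) "YES" else "NO",
    multifocal_extra_adrenal = if (multifocal) "YES" else "NO",
    metastasis = if (metastasis) "YES" else "NO")

  if (cohort == "GERMLINE_ONLY") {
    return(patient_record(
      subject_id = id, cohort = cohort,
      germline_variants = list(germline_variant(germ_text, cls)),
      other_germline = other, other_germline_assessed = TRUE,
      somatic_alterations = list(), somatic_assessed = FALSE,
      clinical = clinical,
      driver_status = driver_gene_status()))
  }

  # fully integrated record: tumor + IHC evidence
  hit <- bern(if (plp) params$p_second_hit_plp else params$p_second_hit_vus)
  som <- list()
  if (hit) {
    som_text <- if (bern(params$p_copy_loss_given_hit)) {
      paste(gene, "One Copy Deletion")
    } else {
      sprintf("%s:c.%d+1G>A", gene, 3L * sample(20:400, 1L))
    }
    som <- list(somatic_alteration(som_text))
  } else if (bern(params$p_copy_gain)) {
    som <- list(somatic_alteration(paste(gene, "Copy Number Gain")))
  }
  if (hit && bern(params$p_ihc_concordant_given_hit)) {
    ihc_a <- if (gene == "SDHA") "LOSS" else "NOT_TESTED"
    ihc_b <- "LOSS"
  } else {
    ihc_a <- "NOT_TESTED"
    ihc_b <- "NOT_TESTED"
  }

  patient_record(
    subject_id = id, cohort = cohort,
    germline_variants = list(germline_variant(germ_text, cls)),
    other_germline = other, other_germline_assessed = TRUE,
    somatic_alterations = som, somatic_assessed = TRUE,
    clinical = clinical,
    driver_status = driver_gene_status(
      kit = if (bern(params$p_kit_pdgfra_mut)) "MUTATED" else "WT",
      pdgfra = "WT"),
    ihc_sdha = ihc_a, ihc_sdhb = ihc_b)
}

#' Analytic expectations for the cohort summary of a generated cohort
#'
#' Closed-form expected values (linearity of expectation over the stated
#' generator probabilities) for every [summarize_cohort()] count of a
#' generated integrated cohort of size `n`. These expectations are the
#' oracle against which the generator's empirical rates are tested.
#'
#' @param params A [synthetic_cohort_params()] object.
#' @param n Cohort size (default: the scaled cohort-1 size).
#' @param frac_plp Pathogenic fraction (default from `params`); pass `1` for
#'   expectations over a purely pathogenic cohort.
#' @return Named numeric vector of expected counts.
#' @export
expected_counts <- function(params, n = round(params$n_cohort1 / params$scale),
                            frac_plp = params$frac_plp) {
  f <- frac_plp
  p_pers <- f * params$p_personal_plp + (1 - f) * params$p_personal_vus
  p_fam <- f * params$p_family_plp + (1 - f) * params$p_family_vus
  p_hit <- f * params$p_second_hit_plp + (1 - f) * params$p_second_hit_vus
  p_none <- (1 - p_hit) * (1 - params$p_copy_gain)
  c(n_records = n,
    n_plp = n * f,
    n_personal_history = n * p_pers,
    n_family_history = n * p_fam,
    n_somatic_inactivating = n * p_hit,
    n_copy_loss_second_hit = n * p_hit * params$p_copy_loss_given_hit,
    n_snv_second_hit = n * p_hit * (1 - params$p_copy_loss_given_hit),
    n_no_somatic_alteration = n * p_none,
    n_ihc_concordant_among_second_hit =
      n * p_hit * params$p_ihc_concordant_given_hit)
}

#' Generate split source tables for the integrated-database merge
#'
#' Produces the germline-side and tumor-side source tables that
#' [merge_isgd()] joins: every generated record contributes its
#' germline/clinical columns to the germline source (cohorts 1 and 2) and
#' its tumor columns to the tumor source (cohorts 1 and 3), so the id
#' overlap between the two sources is exactly the integrated cohort.
#'
#' @param params A [synthetic_cohort_params()] object.
#' @return List with data frames `germline` and `tumor`.
#' @export
generate_isgd_sources <- function(params) {
  recs <- generate_cohort(params)
  tab <- do.call(rbind, lapply(recs, record_to_row))
  g_cols <- c("subject_id", "germline_variants", "germline_classification",
              "other_germline", "personal_history", "parent_of_origin",
              "family_history", "multifocal", "metastasis", "diagnoses")
  t_cols <- c("subject_id", "somatic_alterations", "kit_status",
              "pdgfra_status", "ihc_sdha", "ihc_sdhb")
  list(germline = tab[tab$cohort %in% c("GERMLINE_AND_TUMOR", "GERMLINE_ONLY"),
                      g_cols, drop = FALSE],
       tumor = tab[tab$cohort %in% c("GERMLINE_AND_TUMOR", "TUMOR_ONLY"),
                   t_cols, drop = FALSE])
}
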