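# Packaged reference cohort fixtures: machine-readable transcriptions of the
# five fully-integrated cohort analysis tables (pathogenic/likely-pathogenic
# SDHx carriers and the per-gene VUS analyses), shipped in the cohort table
# format so the reader is exercised on real in-table content.

FIXTURE_IDS <- c(T4 = "cohort-t4.tsv", T5 = "cohort-t5.tsv",
                 T6 = "cohort-t6.tsv", T7 = "cohort-t7.tsv",
                 T8 = "cohort-t8.tsv")

#' Load a packaged reference cohort fixture
#'
#' The five fixtures transcribe the published integrated-cohort analysis
#' tables for subjects with both germline and tumor testing: `"T4"` the 37
#' pathogenic/likely-pathogenic SDHx carriers, `"T5"` the 40-record SDHA VUS
#' analysis, `"T6"` the 15-record SDHB VUS analysis, `"T7"` the 10-record
#' SDHC VUS analysis, and `"T8"` the 7-record SDHD VUS analysis. Field values
#' are transcribed verbatim, including equivocal stains, not-tested markers
#' and copy-number-gain annotations.
#'
#' @param table_id One of `"T4"`, `"T5"`, `"T6"`, `"T7"`, `"T8"`.
#' @return List of `patient_record` objects (see [read_cohort_table()]).
#' @export
#' @examples
#' length(load_fixture("T4"))
load_fixture <- function(table_id) {
  if (!is.character(table_id) || length(table_id) != 1L ||
      !table_id %in% names(FIXTURE_IDS)) {
    stop("unknown fixture id; use one of: ",
         paste(names(FIXTURE_IDS), collapse = ", "))
  }
  path <- system.file("extdata", FIXTURE_IDS[[table_id]],
                      package = "hppglintegrate")
  read_cohort_table(path)
}
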