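Package: hppglintegrate
Title: Integrated Germline and Tumor Evidence Assessment for Hereditary
    Paraganglioma-Pheochromocytoma Syndromes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A rule-based engine for the integrated assessment of germline
    SDHx variants in hereditary paraganglioma-pheochromocytoma syndromes
    (HPPGL). Combines germline variant data, clinical-genetics history,
    tumor-derived evidence (somatic second hits under the two-hit model,
    KIT/PDGFRA status) and SDHA/SDHB immunohistochemistry into framework
    categories with standardized comments. Includes batch cohort
    processing over delimited tables, an integrated somatic-and-germline
    merge, cohort summary analytics, ClinVar-style submission payload
    generation with a PHI guard, packaged reference cohort fixtures, and
    a seeded synthetic-cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
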