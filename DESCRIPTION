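Package: ctdnafp
Title: Patient-Specific ctDNA Fingerprint Panels for Treatment-Response
    Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Designs patient-specific circulating tumor DNA (ctDNA)
    "fingerprint" amplicon panels from tumor whole-exome somatic variant
    tables by clustering clonal populations and selecting the top clonal
    SNVs; quantifies tumor burden per blood draw as the ctDNA content
    fraction (CCF), the doubled mean mutant-allele fraction across panel
    targets, behind sequencing-run QC gates; calibrates detection
    thresholds and panel-level sensitivity/specificity from reference
    standard dilution series, both analytically (normal approximation)
    and by Monte Carlo; and monitors longitudinal treatment response via
    the fold change of CCF between the definitive ctDNA test (at or just
    before clinical imaging) and its immediate predecessor, with hotspot
    drug-resistance screening. Ships a synthetic-data module that
    generates cohorts, reference replicates and CCF trajectories so the
    whole pipeline runs without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    mclust,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
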