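Package: chbarcode
Title: Mutational Barcode Detection of Clonal Hematopoiesis from Cohort
    Whole-Genome Variant Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects clonal hematopoiesis (CH) in blood whole-genome
    sequencing cohorts from the mutational barcode carried by an expanded
    hematopoietic clone: cohort-singleton variants at low variant allele
    fraction (VAF 0.10-0.25) are counted per sample, the germline
    contamination of that window is estimated with a depth- and
    sequencing-center-stratified ratio model fitted on the symmetric
    high-VAF window, and samples whose estimated somatic singleton count
    exceeds a center/platform-calibrated threshold are called CH.
    Includes candidate preleukemic driver (CPLD) and CHIP filter cascades
    with an exact binomial germline test, CH subtype classification,
    study exclusion criteria, Fisher's exact per-variant tests,
    covariate-adjusted logistic associations, inverse-variance-weighted
    effect-on-effect regression, and a synthetic cohort generator with
    known ground truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
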