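Package: imprintscan
Title: Mapping Imprinted Differentially Methylated Regions from
    Parental-Dosage Methylation Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide discovery of imprinted differentially
    methylated regions (DMRs) from promoter methylation beta-value arrays of
    tissues with unbalanced parental genome dosage (diandric and digynic
    triploid placentas, complete hydatidiform moles, biparental controls).
    Provides a from-scratch implementation of the SAM permutation statistic
    (two-class and multiclass) with fudge-factor regularization and
    permutation-based false discovery rates, a candidate screen with
    parental-origin assignment and reference-pattern consistency filtering,
    DMR aggregation and tissue/gestational-age classification, parent-of-origin
    allelic-expression validation logic, and a synthetic beta-matrix generator
    implementing the haploid-genome-dosage model for calibration and recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
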