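Package: plasmacnv
Title: Fetal Copy-Number Variant Screening from Low-Coverage Maternal Plasma Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for noninvasive prenatal screening of
    fetal copy-number variants (CNVs) from low-coverage whole-genome sequencing of
    maternal plasma cell-free DNA. Provides a multinomial read-count simulator with
    a maternal/fetal mixture model, GC bias and sex-chromosome dosage; regression
    based GC correction of binned coverage; chromosome-Y fetal-fraction estimation
    against male and female reference regressions; a CNV caller built on binary
    segmentation with a fetal-fraction-aware dynamic threshold; and a concordance
    evaluator that parses karyotype/microarray findings, classifies calls as
    consistent, partly consistent or inconsistent by interval overlap, and computes
    stratified sensitivity, specificity and positive predictive value with exact
    binomial confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
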