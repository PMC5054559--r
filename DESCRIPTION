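Package: gestclock
Title: Gestational-Age Methylation Clocks from Cord-Blood DNA Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates gestational-age (GA) prediction clocks from
    cord-blood DNA methylation beta values. Provides a two-batch synthetic
    cohort generator with planted GA effects and cell-type mixture structure,
    an epigenome-wide association scan based on MM-type robust linear
    regression with Bonferroni and Benjamini-Hochberg correction,
    reference-based (Houseman-style) cell-type deconvolution by constrained
    least squares, penalized-regression clock training with cross-validated
    penalty selection, robust-regression evaluation of predictions (R-squared
    and 95 percent prediction-interval half-width in days), and set arithmetic
    over CpG and gene lists for comparing clocks with external studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    generics,
    glmnet,
    pracma,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    jsonlite
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
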