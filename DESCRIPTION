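Package: coosig
Title: Cell-of-Origin Expression Signatures for Ovarian Tumor Stratification
Version: 0.1.0
Authors@R: person("Repo", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Derives a fallopian-tube versus ovarian-surface-epithelium
    differential expression signature from a paired two-patient cell-line
    design (consensus intra-block correlation, per-gene generalized least
    squares, empirical-Bayes moderated t statistics, Benjamini-Hochberg FDR),
    scores tumor expression profiles with +1/-1 gene weights, stratifies
    tumors into FT-like and OV-like subgroups with a two-component Gaussian
    mixture chosen by BIC, and tests the stratification against ordinal and
    categorical clinical covariates and survival, including a
    permuted-signature null control. Ships a synthetic-data module that
    generates paired cell-line designs and tumor cohorts with known truth so
    the whole pipeline is testable without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    jsonlite
Config/testthat/edition: 3
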