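Package: episig
Title: Peripheral-Blood DNA Methylation Epi-Signature Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for deriving and applying peripheral-blood
    DNA methylation epi-signatures of Mendelian disorders from methylation array
    beta values, with an X-linked carrier class showing an intermediate effect.
    Provides quality filtering of probes and samples, beta/M-value transforms,
    reference-based blood cell-composition estimation, moderated per-probe
    differential methylation with empirical-Bayes variance shrinkage,
    bump-hunting detection of differentially methylated regions with bootstrap
    family-wise error rates, selection of a non-redundant fully separating probe
    subset, and a three-class support vector machine emitting per-class
    probability scores. A synthetic-cohort generator plants configurable probe
    and region effects (full effect in patients, a configurable fraction in
    heterozygous carriers) so the whole pipeline is testable without microarray
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    limma,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
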