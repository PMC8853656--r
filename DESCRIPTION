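Package: methylpace
Title: Pace-of-Aging Phenotyping and DNA Methylation Biomarker Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for constructing a longitudinal Pace of Aging phenotype
    from repeated biomarker panels via linear mixed-effects growth models,
    distilling it into a sparse CpG-weight scoring algorithm with
    reliability-filtered elastic-net regression, applying the score to new
    DNA methylation datasets through quantile normalization against a frozen
    reference probe panel, and evaluating reliability (intraclass
    correlation) and validity (age acceleration, Klemera-Doubal biological
    age, Phenotypic Age, homeostatic dysregulation, effect sizes). Includes
    synthetic-data generators that plant known latent pace, CpG signal and
    probe-level reliability so every stage can be exercised and validated
    without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    jsonlite,
    lme4,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
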