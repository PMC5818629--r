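Package: bmdrank
Title: Benchmark Dose Modelling and Cross-Tissue Sensitivity Ranking for
    Genetic Toxicology
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Fits the nested exponential family of dose-response models to
    continuous and count-derived genetic toxicology endpoints (DNA adducts,
    transgene and Pig-a mutant frequencies, micronucleus frequencies),
    selects a model by nested likelihood-ratio testing, and derives
    benchmark doses (BMD) with two-sided profile-likelihood confidence
    intervals. Also provides Poisson-regression trend tests with per-dose
    contrasts, confidence-interval-overlap sensitivity ranking across
    tissues, cross-endpoint BMD comparison, unity-slope proportionality
    analysis between endpoint BMDs, and a seeded generator of study-like
    synthetic datasets so the whole pipeline can be exercised and validated
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    lhs,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
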