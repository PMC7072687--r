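Package: mrmcad
Title: Multi-Reader Multi-Case ROC Analysis for CAD Reader Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-reader multi-case (MRMC) reader
    studies of computer-aided diagnosis (CAD) systems, motivated by
    thyroid-nodule ultrasound reading. Provides single-reader ROC
    machinery (empirical operating points, Wilcoxon AUC, maximum-likelihood
    binormal curve fitting, partial AUC, sensitivity and specificity at
    fixed operating points), Dorfman-Berbaum-Metz jackknife pseudovalue
    ANOVA with the Hillis degrees-of-freedom correction for modality
    comparison, interobserver score-variability summaries, a directional
    contour match-ratio metric for segmentation quality, and a
    Roe-Metz-style latent-variable simulator for generating fully crossed
    rating data and contour pairs. All user-facing functions take data
    frames and return tibbles.
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
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
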