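Package: thinpatch
Title: Normative Thin-Patch-Fraction Modeling of Cortical Thickness and
    Domain-Specific Progression Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patch-wise normative modeling of cortical thickness against an
    age- and sex-matched reference cohort: per-patch z-scores, exact rank
    permutation p-values, "significantly thin" patch calls and the
    thin-patch fraction (TPF) over whole-brain or domain-specific patch
    sets. Includes projection of functional network masks onto a
    1000-patch cortical parcellation, covariate-adjusted linear models
    relating TPF to clinical motor and cognitive scores with adjusted-R2
    model comparison, progressor dichotomization with exact tie-aware
    Wilcoxon signed-rank tests, an RBF-kernel support vector machine
    progression classifier with train/test splitting, filter feature
    selection and five-fold cross-validated hyperparameter tuning, and a
    seeded synthetic-cohort generator emulating a normative repository and
    an early Parkinson's disease patient cohort so the full pipeline is
    testable without restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    matrixStats,
    quadprog,
    stats,
    tools,
    truncnorm,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
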