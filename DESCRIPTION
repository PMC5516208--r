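Package: ohctreat
Title: Treatment Mention Extraction and Attribution in Online Health Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint extraction of treatment mentions and their attribution
    (patient-used, patient-generic, caregiver, others, generic) from
    online-health-community forum posts, using a linear-chain conditional
    random field over a typed-BIO tag alphabet with lexical, semantic
    (gazetteer) and syntactic features. Includes dictionary-matching and
    lasso logistic-regression baselines, span-level evaluation in three
    regimes with Cohen's kappa for annotator agreement, per-user treatment
    catalogues with cross-sectional frequency tables, longitudinal
    mention-frequency series aligned to each member's join date, and a
    seeded synthetic forum-corpus generator that produces gold-annotated
    data for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    glmnet,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
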