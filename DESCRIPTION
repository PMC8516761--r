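Package: grievlex
Title: Construction, Scoring, and Validation of Multi-Category
    Rating-Weighted Psycholinguistic Lexicons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and applying word-count based
    psycholinguistic dictionaries in which every (term, category) pair
    carries a crowd-assigned goodness-of-fit rating on a 0-10 scale.
    Implements proportional and rating-weighted document scoring over
    stemmed tokens (including multiword phrases), a construction
    pipeline that expands seed words through lexical relations and
    embedding nearest neighbours and aggregates crowd ratings to word
    stems, psychometric evaluation of category wordlists (Cronbach's
    alpha, correlations with a reference dictionary under Bonferroni
    control), bootstrap down-sampled group comparisons with Cohen's d
    and Jeffreys-Zellner-Siow Bayes factors, and a classification
    harness (multinomial naive Bayes, linear SVM, random forest) with
    ROC-based feature importance. Synthetic fixture generators emulate
    every input so the full toolchain is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    stringi,
    jsonlite,
    e1071,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma,
    knitr,
    rmarkdown
Config/testthat/edition: 3
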