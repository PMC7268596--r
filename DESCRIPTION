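Package: screensim
Title: Retrospective Simulation of Machine-Learning-Assisted Title and
    Abstract Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study semi-automated study selection for systematic
    and rapid reviews. Provides a data model and RIS/CSV input-output for
    citation records and reviewer decisions, a synthetic citation-corpus
    generator with imperfect reviewers and a citation graph, an
    active-learning relevance classifier (regularised logistic regression
    on bag-of-words features with labeled-term priors) standing in for
    screening tools such as Abstrackr, the four automated and
    semi-automated single- and dual-reviewer screening strategies, the
    proportion-missed / workload-savings / time-savings metric calculus
    with 2x2 cross-tabulations, and a cited-references recovery stage that
    checks whether missed records are reachable from retained included
    studies' reference lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    Matrix,
    stats,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
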