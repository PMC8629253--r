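Package: raschcut
Title: Standard Setting for Low Proficiency with Bookmark Cut Scores and
    Constrained Mixture Rasch Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparing judgement-based and model-based
    standard-setting procedures on scored reading-competence tests.
    Implements marginal maximum likelihood estimation of a weighted
    partial credit model with weighted likelihood (WLE) person scores
    and test-quality diagnostics (infit, adjusted Q3, marginal
    reliability); a constrained mixture Rasch model (discrete latent
    proficiency classes with class-invariant item parameters and zero
    within-class variance) estimated by EM with random restarts; class
    enumeration via AIC, BIC, sample-adjusted BIC, a bootstrapped
    likelihood ratio test, relative entropy and average posterior class
    probabilities; bookmark cut scores from difficulty-ordered item
    booklets at a configurable response probability; and a full 2x2
    classification-agreement suite (McNemar's test, Cohen's kappa,
    sensitivity, specificity, within-proficiency disagreement rates).
    A synthetic-data module generates item banks and response matrices
    with the continuous-ability and discrete-class structures the
    models assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
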