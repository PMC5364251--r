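Package: wecint
Title: Weighted Effect Coding and Orthogonal Interaction Contrasts for
    Unbalanced Designs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builders for dummy, effect, and weighted effect coding of
    categorical predictors, including weighted-effect-coded interaction
    variables for two-way cross-classifications. Weighted effect coding
    parameterizes regression coefficients as deviations from the
    count-weighted sample mean, the natural baseline for unbalanced
    observational data; its interaction columns are constructed to be
    exactly orthogonal to the intercept and main-effect columns, so adding
    them leaves the main effects of the interaction-free model unchanged.
    The package fits linear and generalized linear models on the coded
    columns from raw observations or from cell-level sufficient statistics
    (counts and means), recovers coefficients for omitted reference
    categories by refitting with cross-checked sum-to-zero constraints,
    generates unbalanced synthetic two-factor data, and ships a built-in
    worked example on body mass index across parenthood and age groups
    that reproduces a published coefficient table from its printed counts
    and coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
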