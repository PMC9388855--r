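Package: vaefa
Title: Nonlinear Exploratory Factor Analysis of Questionnaires with
    Variational Autoencoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exploratory factor analysis of Likert-type questionnaire data
    with variational autoencoders (VAE) and a complete linear factor
    analysis (LFA) baseline, so the two can be compared on the same data.
    Provides masked-Gaussian ELBO training with validation-based early
    stopping, input-reconstruction correlation and R-squared accuracy
    metrics, multi-run factor stability analysis via congruence-score
    clustering, factor-variable association by muting latent factors, the
    significant-factor-limit search (SFLS) for choosing the number of
    factors, principal-axis factoring with varimax rotation and
    Thurstone/Bartlett factor scores, and a seeded generator of synthetic
    questionnaire data with known latent structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
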