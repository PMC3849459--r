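Package: labrec
Title: Bayesian Co-Occurrence Recommendation of Clinical Laboratory Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks candidate clinical laboratory tests for a patient given the
    tests already taken, using a naive-Bayes log-odds weighting function
    estimated from a symmetric test-by-test co-occurrence matrix. Includes
    language-model style smoothing of the conditional probabilities
    (Jelinek-Mercer, Dirichlet prior, absolute discounting) and Laplace
    smoothing of the prior log-odds, a reader for delimited laboratory-record
    files, a seeded split / remove-label / top-X hit-rate evaluation framework
    (CorrectRate_X), a synthetic patient-visit generator with latent condition
    panels for end-to-end testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
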