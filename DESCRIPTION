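Package: bilexr
Title: Neural-Network Patient Models of Bilingual Lexical Access and
    Treatment Response
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A three-map self-organizing-map model of the bilingual mental
    lexicon with Hebbian cross-map associative connections. Models are
    trained to an individual's bilingual exposure history, lesioned by unit
    deletion to reproduce poststroke semantic and picture-naming scores,
    and retrained under a parameterized semantic-feature treatment protocol
    whose six parameters are fitted to naming-probe trajectories with an
    evolutionary algorithm and validated by leave-one-out cross-validation.
    Includes a synthetic bilingual lexicon generator, lesion-fitting and
    treatment-simulation tools, and evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
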