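Package: antcontext
Title: Contextuality Analysis of Collective Nest-Site Choice in Ant Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates collective nest-site emigration by ant colonies and tests
    the resulting choice probabilities for contextuality in the sense of the
    Contextuality-by-Default (CbD) theory of cyclic systems. Provides a
    Monte-Carlo agent-based emigration simulator with heterogeneous acceptance
    thresholds, a deterministic infinite-population colony-choice model, the
    high-threshold joint-probability construction with bootstrap standard
    errors, CHSH-type and CbD contextuality statistics for cyclic systems of
    arbitrary rank, an independent coupling-feasibility oracle, and reference
    fixtures (PR box, Tsirel'son, classical mixtures, an intransitive
    ice-cream preference cycle) with known contextuality status.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
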