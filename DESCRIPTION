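Package: lossrange
Title: Range Effects in Mixed-Gamble Acceptance and the Reliability of
    Loss-Aversion Estimates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the range of gains and losses experienced
    in an accept-reject task shapes the acceptance of 50-50 mixed gambles, and
    for probing whether prospect theory's loss-aversion coefficient (lambda)
    can be recovered from such choices. Implements rank-based valuation in the
    style of decision by sampling, a reduced prospect-theory accept-reject
    choice model with loss aversion and an accept/reject bias, per-agent
    multi-start maximum-likelihood estimation, synthetic agent populations
    under well-specified and misspecified generators, model-free accept
    proportions on gambles common to all conditions, and the split-half
    rank-generalization experiment with its stochasticity-only null.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
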