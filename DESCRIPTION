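Package: ipnn
Title: Interval Probabilistic Neural Networks for Classifying Imprecise Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Nonparametric Bayes classification of interval-valued (imprecise)
    query items against classes described by precisely measured pattern
    samples.  Class densities are estimated with Cauchy-kernel product
    estimators whose per-dimension smoothing parameters come from a
    three-stage plug-in selector, optionally sharpened by sample-point
    adaptive bandwidth modification.  Because the Cauchy kernel has a
    closed-form antiderivative, the probability mass of a query
    hyper-rectangle is computed analytically and the Bayes decision for an
    interval vector costs no more than a crisp probabilistic-neural-network
    evaluation.  Includes a counting-rule baseline, seeded Monte-Carlo error
    experiments for Gaussian and Gaussian-mixture designs, CSV/JSON model
    input and output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
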