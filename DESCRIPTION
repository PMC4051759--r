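Package: lianevol
Title: Phylogenetic Divergence and Trait Evolution in Lianas and Trees
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative phylogenetic analysis contrasting woody climbers
    (lianas) and trees: age calibration of backbone phylogenies by even
    interpolation (BLADJ-style smoothing), stochastic character mapping of
    the growth-form character under a two-state Markov model, maximum
    likelihood estimation of single-rate and state-dependent Brownian
    motion rates of trait evolution with profile-likelihood confidence
    intervals and likelihood ratio tests, standardized effect sizes of
    mean pairwise phylogenetic and trait distance under label-shuffling
    nulls, and phylogenetic signal via Blomberg's K (permutation test on
    contrast variance) and Pagel's lambda (likelihood ratio test against
    lambda = 1).  Includes a calibrated synthetic-data generator so the
    whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phytools,
    picante,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
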