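Package: svoconform
Title: Cognitive Modelling of Social-Attitude Conformity in Resource-Allocation Games
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how people's social value orientation (SVO)
    shifts after observing the allocation choices of extreme prosocial or
    antisocial agents. Generates the circle-band allocation task, simulates
    populations of participants across four observation conditions, fits six
    hierarchical Bayesian cognitive choice models (Stable Attitude softmax and
    Variable Attitude random-preference families, each with full, tied-attitude
    and tied-variability variants) by Markov chain Monte Carlo, compares them
    by the deviance information criterion, derives conformity and compliance
    measures (attitude convergence, polarisation, compliance index, consistency
    change), and runs the accompanying nonparametric and Bayes-factor test
    battery end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
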