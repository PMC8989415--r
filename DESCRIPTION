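Package: isingdict
Title: Irreducible Dictionaries of Anomalous Binary Patterns via a
    Bayesian Ising Indicator Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects statistically over- or under-represented binary
    patterns ("words") of arbitrary order in M x N binary data, such as
    discretised neural spike trains jointly recorded with a binary
    behavioural readout. Candidate patterns receive a magnetic field
    measuring the deviation of their empirical frequency from an
    independent-unit null model, and exchange couplings between
    overlapping patterns implement competition so that the extracted
    dictionary is irreducible. The indicator-variable Ising model is
    solved by naive mean field along a regularisation schedule, detection
    thresholds are calibrated against column-shuffled null data, and a
    log-linear generative benchmark with planted higher-order
    interactions scores precision and recall. Includes a front end for
    binarising spike-time trial data against acoustic or other scalar
    behavioural features, and a ridge-penalised logistic comparison of
    behaviour prediction from raw time bins versus detected codewords.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
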