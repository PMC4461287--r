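Package: boolprune
Title: Contextualization of Signed Regulatory Networks by Boolean Attractor Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prunes a signed, directed prior-knowledge network (PKN) so that the
    fixed points of its synchronous Boolean model reproduce a pair of observed
    stable phenotypes. Candidate subnetworks are scored by the normalized
    Hamming distance between each Booleanized phenotype and the attractor
    reached from it, and the edge set is optimized with a univariate
    estimation-of-distribution evolutionary algorithm. Includes a random-search
    baseline, repeated random sub-sampling cross-validation for missing
    expression value prediction, sensitivity analyses for missing or wrong
    training states, transient perturbation simulation, and a planted-truth
    synthetic fixture generator for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
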