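Package: nammap
Title: Multi-Locus QTL Mapping for Nested Association Mapping Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint multi-family QTL mapping for nested association mapping
    (NAM) populations of recombinant inbred lines that allows a locus to carry
    a different additive effect in every half-sib family. Per-marker genotype
    classes are recoded by their family-specific phenotype deviations into a
    single incidence vector, all markers are fit jointly with an
    empirical-Bayes EM shrinkage estimator, and surviving effects are
    validated by likelihood-ratio tests on a maximum-likelihood refit with a
    LOD threshold. Includes a RIL genotype/phenotype simulator for half-sib
    family designs and an evaluation layer scoring detection power, false
    positive rate, and position/effect bias against simulated truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
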