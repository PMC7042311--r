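Package: mutdist
Title: Per-Division Mutation and Cell Survival Rates from Mutational Distances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint inference of the per-cell-division mutation rate and the
    per-cell survival rate of a growing tissue from multi-region or
    single-cell somatic sequencing data. The distribution of mutational
    distances between reconstructed ancestral cells is modelled as a
    compound of Poisson mutation accrual, negative-binomial non-branching
    divisions and a coalescent-derived distribution of branching divisions
    in an exponentially expanding cell population. Parameters are inferred
    with a Metropolis-Hastings sampler. A stochastic (optionally spatial)
    Gillespie tissue simulator with lineage recording, biopsy sampling and
    sequencing-noise synthesis provides the validation substrate, and
    mutational-signature stratification supports per-signature rate
    estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    pracma,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
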