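Package: epibound
Title: Bound-Guided Bayesian Search for Strict Epistatic Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects strict epistatic interactions in case-control genotype
    data by scoring SNP patterns (small Bayesian networks with SNP nodes as
    parents of a disease node) with the BDeu marginal likelihood, and by
    computing an upper bound on the score of any pattern obtainable by adding
    SNPs to a given pattern. Sorting SNPs by this expansion bound lets a
    combinatorial search locate interacting loci that show no marginal effect
    after examining a small fraction of the search space. Includes a
    GAMETES-style simulator of strict (no proper subset of the interacting
    loci has a marginal effect) penetrance models under Hardy-Weinberg
    equilibrium, with heritability and minor-allele-frequency control, and an
    experiment driver that reproduces the simulation study at configurable
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    ggplot2,
    rlang,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
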