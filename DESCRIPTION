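Package: ptmnet
Title: Partition Representation of Enzymatic Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents networks of Michaelis-Menten-type post-translational
    modification (PTM) reactions as set partitions of their substrates,
    enzymes and products. From a partition the package derives the merged
    mass-action ODE system and its conservation laws with multiplicities,
    counts and enumerates all networks of a given size (Bell numbers),
    measures a metric distance between partitions, scores resettable
    bistability by Monte-Carlo steady-state sweeps of an input enzyme's
    total concentration, and searches partition space for high-scoring
    topologies with a recursive stochastic algorithm built on two partition
    modifiers (separate and join).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tidyr,
    withr,
    xml2
Config/testthat/edition: 3
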