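Package: scipso
Title: Hybrid Gene Selection with Gene Scoring and Improved Particle Swarm Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Selects small, highly discriminative gene subsets from labelled
    expression matrices (samples by genes) using a three-level filter cascade
    followed by a wrapper search. Level one ranks genes by the information
    index to classification (IIC), a per-gene class-separability statistic;
    level two screens randomly drawn gene subsets by stratified 5-fold
    cross-validation accuracy of an extreme learning machine (ELM); level
    three scores genes by the ranks of the surviving subsets that contain
    them. An improved particle swarm optimizer then searches the resulting
    gene pool, using a Metropolis acceptance rule under a linearly decreasing
    annealing temperature to update the swarm's best position and
    reinitializing half of the swarm after a fixed number of stagnant
    generations. Includes a synthetic microarray generator with planted
    informative genes, repeated-run frequency reports, parameter sweeps and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
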