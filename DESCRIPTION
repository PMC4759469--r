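Package: swarmraft
Title: Degree-Capped Random Graph Models of Density Thresholds in Swarming Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Models the formation of multicellular rafts in swarming bacterial
    populations (e.g. Proteus mirabilis) as random graph processes on a fixed
    set of cells in which every cell can touch at most two neighbours, so that
    every connected component is a simple chain or loop of cells. Provides
    three stochastic update rules (one edge candidate per timestep; a
    Bernoulli sweep over all cell pairs; the same sweep with random cell
    death), trajectory observables (average degree, giant component,
    component-size distributions, hitting times of a threshold component),
    a closed-form hitting-time theory for the time at which a population
    first assembles a chain of a given size, an exact Markov-chain oracle for
    small populations, and a gamma-distribution matching layer that relates
    gamma fits of empirical hitting times to the underlying density threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    MASS,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
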