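Package: neurofield
Title: Hybrid Classical-Quantum Neural-Field Network Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of fitness-driven growing networks used as
    models of cognitive-emotional neural fields. Grows preferential-attachment
    networks whose node fitnesses map to energy levels, computes occupation
    numbers under Maxwell-Boltzmann, Bose-Einstein and Fermi-Dirac statistics,
    solves for the chemical potential and detects Bose-Einstein condensation,
    implements Hebbian and quantum plasticity rules, Arrhenius transition
    kinetics with work-energy accounting, classifies three-dimensional
    state-space trajectories by winding numbers, spectral coherence and Wolfram
    class, and maps networks onto potential landscapes and graph-Laplacian
    eigenmodes. All inputs can be generated by deterministic fixture
    generators; networks, trajectories and rate series round-trip through
    GraphML and CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    pracma,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
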