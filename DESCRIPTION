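Package: evowire
Title: Multi-Objective Evolution of Reservoir Wiring Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evolves the internal wiring of small echo-state reservoirs with
    NSGA-II under competing structural and functional objectives: maximizing
    binned transfer entropy from input units to readout units while minimizing
    spatial wiring cost and connection density. Includes generators for
    natural-image-like saccadic stimulus series and oriented probe stimuli,
    subtractive-normalized Hebbian plasticity for prenatal-style tuning and
    readout training, structural metrics (grid coupling cost, density, Newman
    modularity, clustering, path length) and dynamical characterization of
    evolved circuits (transfer-entropy maps, PCA trajectory embedding, k-means
    stimulus separation, box-counting fractal dimension, trajectory volume).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
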