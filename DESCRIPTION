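Package: gestaltsync
Title: Spike Synchrony and Gestalt Structure in a V1-Like Excitatory Spiking Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying zero-lag spike
    synchrony (Rsync) in a fully excitatory, pulse-coupled Izhikevich
    spiking network with V1-like lateral connectivity. Generates
    two-segment Gestalt stimuli (proximity, similarity, continuity),
    decomposes them into orientation channels, encodes them as Poisson
    spike input, integrates the network with receptor/transmitter
    synapse kinetics, measures group and average pairwise Rsync, and
    runs the nonparametric statistical comparisons (Wilcoxon rank-sum,
    Kruskal-Wallis with Dunn/Bonferroni post hoc, Pearson correlation
    of synchrony with connectivity strength) together with spike-time
    jitter and lateral-ablation controls.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'params.R'
    'stimuli.R'
    'stimuli-io.R'
    'connectivity.R'
    'RcppExports.R'
    'simulator.R'
    'synchrony.R'
    'experiments.R'
    'replication.R'
    'gestaltsync-package.R'
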