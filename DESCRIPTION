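Package: gabanet
Title: Spiking Network Model of the Developmental GABA-A Switch
Version: 0.1.0
Authors@R:
    person("Ana", "Keller", email = "ana.keller@posteo.net", role = c("aut", "cre"))
Description: Conductance-based leaky integrate-and-fire network model of
    developing cortex with an immature/mature GABA-A reversal-potential
    switch, Gaussian distance-dependent connectivity on a periodic lattice,
    distance-dependent conduction delays, independent Poisson drive and
    Tsodyks-Markram short-term plasticity (two depressing and two
    facilitating variants).  Includes the downstream analysis pipeline:
    mean spike frequency with burn-in, percent modulation and
    predicted/unpredicted classification, oscillation-band labelling,
    Gaussian PDF trial filtering, van Rossum spike-distance matrices,
    developmental-stage mapping against multi-electrode-array reference
    firing rates, and factorial ANOVA over simulation sweeps, together with
    seed-deterministic synthetic-data generators for testing every analysis
    stage without running the simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
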